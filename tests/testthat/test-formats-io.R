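test_that("HSP VCF reading maps REF/ALT/GT to observed base sets", {
  p <- write_vcf_file(c(
    vcf_row("ref", 10, "A", "C", "0/1"),
    vcf_row("ref", 20, "A", "C,T", "1/2"),
    vcf_row("ref", 30, "A", "CT", "0/1"),   # indel: skipped
    vcf_row("ref", 40, "G", "T", "1/1")
  ))
  expect_message(hsps <- read_hsp_vcf(p), "skipped 1")
  expect_equal(nrow(hsps), 3L)
  expect_equal(attr(hsps, "n_skipped"), 1L)
  expect_equal(hsps$observed_bases[[1]], c("A", "C"))   # GT has 0 -> REF in
  expect_equal(hsps$observed_bases[[2]], c("C", "T"))   # GT lacks 0
  expect_equal(hsps$observed_bases[[3]], "T")           # 1/1, ALT only

  # genotype_rule off: ALT alleles only
  hsps2 <- suppressMessages(read_hsp_vcf(p, genotype_rule = FALSE))
  expect_equal(hsps2$observed_bases[[1]], "C")
})

test_that("SBS VCF reading keeps homozygous SNVs and drops heterozygotes", {
  p <- write_vcf_file(c(
    vcf_row("ref", 5, "G", "T", "1/1"),
    vcf_row("ref", 6, "G", "T", "0/1"),   # heterozygous: ignored
    vcf_row("ref", 7, "G", "TA", "1/1")   # indel: ignored
  ))
  expect_message(sbs <- read_sbs_vcf(p), "ignored 2")
  expect_equal(nrow(sbs), 1L)
  expect_equal(sbs$diploid_base, "T")
  expect_equal(sbs$pos, 5L)

  empty <- read_sbs_vcf(write_vcf_file(character(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("malformed VCF input fails with a format error", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c("not a vcf", "at all"), p)
  expect_error(read_hsp_vcf(p), "line 1")
  expect_error(read_sbs_vcf(tempfile(fileext = ".vcf")), "not found")
})

test_that("GFF3 reading returns only gene rows, sorted, with ids", {
  p <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "ref\t.\tgene\t50\t80\t.\t+\t.\tID=gB",
    "ref\t.\tmRNA\t50\t80\t.\t+\t.\tID=gB.1;Parent=gB",
    "ref\t.\texon\t50\t60\t.\t+\t.\tParent=gB.1",
    "ref\t.\tgene\t9\t15\t.\t+\t.\tID=gA"
  ), p)
  genes <- read_gene_intervals(p)
  expect_equal(genes$gene_id, c("gA", "gB"))
  expect_equal(genes$start, c(9L, 50L))
  expect_equal(genes$end, c(15L, 80L))
})

test_that("coverage tables round-trip and reject malformed input", {
  cov <- tibble::tibble(seq_name = "g1", pos = c(101L, 102L),
                        A = c(12L, 0L), C = c(0L, 5L),
                        G = c(3L, 0L), T = c(0L, 5L))
  p <- tempfile(fileext = ".tsv")
  write_coverage_table(cov, p)
  expect_equal(readLines(p)[1], "#seq\tpos\tA\tC\tG\tT")
  expect_equal(read_coverage_table(p), cov)

  # duplicate position rows
  writeLines(c("g1\t101\t1\t0\t0\t0", "g1\t101\t2\t0\t0\t0"), p)
  expect_error(read_coverage_table(p), "duplicate")
  # negative counts
  writeLines("g1\t101\t-1\t0\t0\t0", p)
  expect_error(read_coverage_table(p), "non-negative")
  # empty file -> empty table
  writeLines(character(0), p)
  expect_equal(nrow(read_coverage_table(p)), 0L)
})

test_that("alignment filtering applies MAPQ, orphan and cross-gene rules", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), seq_name = "ref",
                          start = c(1L, 201L), end = c(100L, 300L))
  reads <- data.frame(
    qname = c("a", "a",      # proper pair in g1
              "x", "x",      # mates in different genes -> dropped
              "o",           # orphan of a pair -> dropped
              "m",           # MAPQ 20 -> dropped
              "k",           # MAPQ 21 single-end -> kept
              "n"),          # overlaps no gene -> dropped
    flag = c(67L, 131L, 67L, 131L, 67L, 0L, 0L, 0L),
    pos = c(10L, 40L, 10L, 210L, 10L, 10L, 220L, 150L),
    mapq = c(60L, 60L, 60L, 60L, 60L, 20L, 21L, 60L),
    cigar = "10M",
    seq = "ACGTACGTAC"
  )
  sam <- write_sam_file(reads, seq_len = 400)
  frags <- filter_alignments(sam, genes)
  cnt <- attr(frags, "counts")
  expect_equal(cnt$reads_total, 8L)
  expect_equal(cnt$reads_mapq_dropped, 1L)
  expect_equal(cnt$reads_no_gene, 1L)
  expect_equal(cnt$reads_pair_dropped, 3L)  # x pair + orphan o
  expect_setequal(unique(frags$gene_id), c("g1", "g2"))
  # the proper pair is one fragment covering both mates
  g1_frag <- frags[frags$gene_id == "g1", ]
  expect_equal(length(unique(g1_frag$fragment_id)), 1L)
  expect_setequal(g1_frag$pos, c(10:19, 40:49))
})

test_that("mate overlap conflicts leave positions uncovered, agreements count once", {
  genes <- tibble::tibble(gene_id = "g1", seq_name = "ref",
                          start = 1L, end = 100L)
  # mates overlap on 10..14; read2 differs from read1 at position 12
  reads <- data.frame(
    qname = "p", flag = c(67L, 131L),
    pos = c(6L, 10L), mapq = 60L, cigar = "9M",
    seq = c("AAAACCCCC",   # covers 6..14, positions 10..14 = C
            "CCGCCTTTT")   # covers 10..18, position 12 G conflicts
  )
  sam <- write_sam_file(reads)
  frags <- filter_alignments(sam, genes)
  expect_false(12L %in% frags$pos)          # conflict dropped
  expect_equal(sum(frags$pos == 10L), 1L)   # agreement counted once
  expect_equal(sum(frags$pos == 11L), 1L)
})

test_that("CIGAR deletions leave reference positions uncovered", {
  genes <- tibble::tibble(gene_id = "g1", seq_name = "ref",
                          start = 1L, end = 100L)
  reads <- data.frame(qname = "d", flag = 0L, pos = 11L, mapq = 60L,
                      cigar = "4M3D4M", seq = "ACGTACGT")
  frags <- filter_alignments(write_sam_file(reads), genes)
  expect_setequal(frags$pos, c(11:14, 18:21))
})

test_that("call tables round-trip through the tab writer and reader", {
  fx <- make_worked_fixture()
  res <- run_pipeline(fx$fragments, fx$hsps, fx$genes, fx$sbs,
                      dip_coverage = fx$dip_coverage)
  out <- tempfile()
  paths <- write_outputs(res$calls, out, format = "both")
  tabs <- paths[grepl("\\.tab$", paths)]
  names(tabs) <- sub("\\.tab$", "", basename(tabs))
  back <- read_calls_tab(tabs)
  orig <- res$calls[, c("seq_name", "pos", "ref_base", "subgenome",
                        "diploid_code", "assigned_base",
                        "fully_characterized")]
  orig <- dplyr::arrange(orig, seq_name, pos, subgenome)
  expect_equal(as.data.frame(back), as.data.frame(orig))

  # VCF side: ALT is "." when the assigned base equals REF
  vcf_lines <- readLines(file.path(out, "s1.vcf"))
  body <- vcf_lines[!startsWith(vcf_lines, "#")]
  expect_equal(length(body), 3L)
  f5 <- strsplit(body[1], "\t")[[1]]
  expect_equal(f5[4], "A")
  expect_equal(f5[5], ".")  # s1 carries the reference base
  s2_body <- readLines(file.path(out, "s2.vcf"))
  s2_body <- s2_body[!startsWith(s2_body, "#")]
  expect_equal(strsplit(s2_body[1], "\t")[[1]][5], "G")
  expect_match(s2_body[3], "DIP=<")
})

test_that("positions with no assignment anywhere are absent from outputs", {
  calls <- tibble::tibble(
    seq_name = "ref", pos = rep(c(5L, 9L), each = 2L),
    ref_base = "A", observed_bases = list(c("A", "C")),
    subgenome = rep(c("s1", "s2"), 2L),
    diploid_code = "A",
    assigned_base = c("A", "C", NA, NA),
    fully_characterized = c(TRUE, TRUE, FALSE, FALSE)
  )
  out <- tempfile()
  write_outputs(calls, out, format = "tab")
  lines <- readLines(file.path(out, "s1.tab"))
  expect_equal(length(lines), 1L)
  expect_match(lines, "^ref\t5\t")
})
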