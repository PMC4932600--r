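# A tiny hand-traceable dataset: one gene, three HSP positions, six
# fragments, two subgenomes. Every step of the algorithm can be followed by
# hand on it, and its expected call table ships alongside.

#' Construct the worked example dataset
#'
#' One 30 bp gene with HSPs at positions 5, 15 and 25. Subgenome `s1`
#' carries the reference bases (A, C, G), subgenome `s2` carries G, T, C.
#' Diploid `s1` has no coverage table and no SBSs, so its profile falls
#' back to the reference base everywhere; diploid `s2` has SBSs at 5 and 15
#' and only two reads at position 25, so its profile there is the
#' low-coverage code `<`. Six single-end fragments cover the gene: two full
#' `s1` patterns, one full `s2` pattern, one `s1` pattern linking positions
#' 15-25, one embedded single-position pattern, and one `s2` fragment
#' carrying only position 25 -- whose base can only be placed by the
#' elimination rule of the finalization step.
#'
#' @return A list with elements `genes`, `reference` (a `reference_build`),
#'   `fragments`, `hsps`, `sbs` (named list), `dip_coverage` (named list)
#'   and `expected_calls` (the call table the full pipeline produces with
#'   finalization on).
#' @export
make_worked_fixture <- function() {
  v <- rep(c("A", "C", "G", "T"), length.out = 30)
  v[5] <- "A"; v[15] <- "C"; v[25] <- "G"
  ref_seq <- paste0(v, collapse = "")
  build <- build_reference(c(g1 = ref_seq), gap_length = 0)
  genes <- build$genes

  s1 <- v
  s2 <- v
  s2[5] <- "G"; s2[15] <- "T"; s2[25] <- "C"

  frag_ranges <- list(
    f1 = list(1:20, s1), f2 = list(1:20, s1), f3 = list(1:20, s2),
    f4 = list(10:28, s1), f5 = list(1:8, s1), f6 = list(22:30, s2)
  )
  fragments <- bind_rows(purrr::imap(frag_ranges, function(fr, nm) {
    tibble(fragment_id = match(nm, names(frag_ranges)),
           gene_id = "g1", seq_name = build$seq_name,
           pos = fr[[1]], base = fr[[2]][fr[[1]]])
  }))

  hsps <- tibble(
    seq_name = build$seq_name, pos = c(5L, 15L, 25L),
    ref_base = c("A", "C", "G"),
    observed_bases = list(c("A", "G"), c("C", "T"), c("C", "G"))
  )

  sbs <- list(
    s1 = tibble(seq_name = character(), pos = integer(),
                ref_base = character(), diploid_base = character()),
    s2 = tibble(seq_name = build$seq_name, pos = c(5L, 15L),
                ref_base = c("A", "C"), diploid_base = c("G", "T"))
  )
  dip_coverage <- list(
    s2 = tibble(seq_name = build$seq_name, pos = c(5L, 15L, 25L),
                A = c(0L, 0L, 0L), C = c(0L, 0L, 2L),
                G = c(10L, 0L, 0L), T = c(0L, 10L, 0L))
  )

  expected_calls <- tibble(
    seq_name = build$seq_name,
    pos = rep(c(5L, 15L, 25L), each = 2L),
    ref_base = rep(c("A", "C", "G"), each = 2L),
    subgenome = rep(c("s1", "s2"), 3L),
    diploid_code = c("A", "G", "C", "T", "G", "<"),
    assigned_base = c("A", "G", "C", "T", "G", "C"),
    fully_characterized = TRUE
  )

  list(genes = genes, reference = build, fragments = fragments,
       hsps = hsps, sbs = sbs, dip_coverage = dip_coverage,
       expected_calls = expected_calls)
}

#' Write the worked example dataset to files
#'
#' Writes the fixture of [make_worked_fixture()] as the file set the
#' command-line interface consumes: reference FASTA/GFF3, a single-end SAM,
#' an HSP VCF, per-diploid SBS VCFs and the diploid coverage table.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of file paths.
#' @export
write_worked_fixture <- function(dir) {
  fx <- make_worked_fixture()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- file.path(dir, "ref")
  write_reference(fx$reference, prefix)

  # single-end SAM, one record per fragment
  fr <- fx$fragments |>
    group_by(.data$fragment_id) |>
    summarise(seq = paste0(.data$base[order(.data$pos)], collapse = ""),
              pos = min(.data$pos),
              .groups = "drop")
  sam <- file.path(dir, "poly.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", fx$reference$seq_name,
                   nchar(fx$reference$sequence)))
  body <- sprintf("f%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                  fr$fragment_id, fx$reference$seq_name, fr$pos,
                  nchar(fr$seq), fr$seq, strrep("I", nchar(fr$seq)))
  writeLines(c(hdr, body[order(fr$pos)]), sam)

  hsp_vcf <- file.path(dir, "hsp.vcf")
  write_simple_vcf(
    tibble(seq_name = fx$hsps$seq_name, pos = fx$hsps$pos,
           ref = fx$hsps$ref_base,
           alt = map2_chr(fx$hsps$observed_bases, fx$hsps$ref_base,
                          function(o, r) paste(setdiff(o, r),
                                               collapse = ",")),
           gt = "0/1"),
    hsp_vcf, "polyploid"
  )
  sbs_files <- purrr::imap_chr(fx$sbs, function(s, nm) {
    p <- file.path(dir, sprintf("sbs_%s.vcf", nm))
    write_simple_vcf(
      tibble(seq_name = s$seq_name, pos = s$pos, ref = s$ref_base,
             alt = s$diploid_base, gt = "1/1"),
      p, nm
    )
    p
  })
  cov_file <- file.path(dir, "cov_s2.tsv")
  write_coverage_table(fx$dip_coverage$s2, cov_file)

  invisible(c(fasta = paste0(prefix, ".fa"), gff3 = paste0(prefix, ".gff3"),
              sam = sam, hsp = hsp_vcf, sbs_files,
              cov_s2 = cov_file))
}
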