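# Readers and writers for every external file format the tool touches, plus
# the alignment-level filters applied before any base counting.

vcf_check <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, "##fileformat=VCF")) {
    abort(sprintf("malformed VCF (line 1): missing ##fileformat header in %s",
                  path))
  }
  invisible(path)
}

vcf_read_fix_gt <- function(path) {
  vcf_check(path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(sprintf("failed to parse VCF %s: %s",
                                      path, conditionMessage(e)))
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- NULL
  if (ncol(v@gt) >= 2L && nrow(v@gt) == nrow(fix)) {
    fmt <- strsplit(v@gt[, 1L], ":", fixed = TRUE)
    gt_idx <- vapply(fmt, function(f) match("GT", f), integer(1))
    sample1 <- strsplit(v@gt[, 2L], ":", fixed = TRUE)
    gt <- vapply(seq_along(sample1), function(i) {
      if (is.na(gt_idx[i]) || length(sample1[[i]]) < gt_idx[i]) NA_character_
      else sample1[[i]][gt_idx[i]]
    }, character(1))
  }
  list(fix = fix, gt = gt)
}

gt_alleles <- function(gt) {
  if (is.na(gt)) return(character(0))
  setdiff(strsplit(gt, "[/|]")[[1]], ".")
}

#' Read candidate HSPs from a VCF file
#'
#' Reads a VCF (v4.0+) of candidate homeolog-specific polymorphisms in the
#' polyploid. Only single-nucleotide rows are used; indel/multi-base rows are
#' skipped and counted. The observed base set of a position is the set of ALT
#' alleles, plus the REF allele when `genotype_rule` is on and the GT field
#' contains allele 0 (or no GT field is present) -- variant callers report
#' ALT alleles only, so the REF base of a heterogeneous polyploid position
#' is usually observed too.
#'
#' @param path Path to a VCF file.
#' @param genotype_rule Include REF in `observed_bases` when GT contains
#'   allele 0 or GT is absent. Default `TRUE`.
#'
#' @return A tibble with columns `seq_name`, `pos`, `ref_base` and the
#'   list-column `observed_bases`. The number of skipped non-SNV rows is
#'   attached as attribute `n_skipped`.
#' @export
read_hsp_vcf <- function(path, genotype_rule = TRUE) {
  x <- vcf_read_fix_gt(path)
  fix <- x$fix
  if (nrow(fix) == 0L) {
    out <- tibble(seq_name = character(), pos = integer(),
                  ref_base = character(), observed_bases = list())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  snv <- nchar(fix$REF) == 1L & fix$REF %in% DNA_BASES &
    vapply(alts, function(a) all(nchar(a) == 1L & a %in% DNA_BASES), logical(1))
  n_skipped <- sum(!snv)
  if (n_skipped > 0) {
    inform(sprintf("read_hsp_vcf: skipped %d non-SNV row(s) in %s",
                   n_skipped, path))
  }
  fix <- fix[snv, , drop = FALSE]
  alts <- alts[snv]
  gts <- if (is.null(x$gt)) rep(NA_character_, nrow(fix)) else x$gt[snv]
  observed <- lapply(seq_len(nrow(fix)), function(i) {
    obs <- alts[[i]]
    if (genotype_rule) {
      al <- gt_alleles(gts[i])
      if (length(al) == 0L || "0" %in% al) obs <- c(fix$REF[i], obs)
    }
    sort(unique(obs))
  })
  out <- tibble(
    seq_name = fix$CHROM,
    pos = as.integer(fix$POS),
    ref_base = fix$REF,
    observed_bases = observed
  )
  out <- arrange(out, .data$seq_name, .data$pos)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read diploid single-base substitutions from a VCF file
#'
#' Reads the single-base substitution (SBS) list of one diploid progenitor:
#' positions where the diploid differs from the common reference. Only
#' biallelic SNV rows with a homozygous-ALT (or absent) genotype are kept;
#' heterozygous/ambiguous diploid calls and multi-allelic rows are ignored.
#'
#' @param path Path to a VCF file.
#'
#' @return A tibble with columns `seq_name`, `pos`, `ref_base`,
#'   `diploid_base`, with attribute `n_skipped` counting ignored rows.
#' @export
read_sbs_vcf <- function(path) {
  x <- vcf_read_fix_gt(path)
  fix <- x$fix
  if (nrow(fix) == 0L) {
    out <- tibble(seq_name = character(), pos = integer(),
                  ref_base = character(), diploid_base = character())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  gts <- if (is.null(x$gt)) rep(NA_character_, nrow(fix)) else x$gt
  snv <- nchar(fix$REF) == 1L & fix$REF %in% DNA_BASES &
    nchar(fix$ALT) == 1L & fix$ALT %in% DNA_BASES
  hom <- vapply(gts, function(g) {
    al <- gt_alleles(g)
    length(al) == 0L || all(al == al[1]) && !"0" %in% al
  }, logical(1), USE.NAMES = FALSE)
  keep <- snv & hom & fix$ALT != fix$REF
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    inform(sprintf("read_sbs_vcf: ignored %d non-SNV/heterozygous row(s) in %s",
                   n_skipped, path))
  }
  out <- tibble(
    seq_name = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref_base = fix$REF[keep],
    diploid_base = fix$ALT[keep]
  )
  out <- distinct(arrange(out, .data$seq_name, .data$pos))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read gene intervals from a GFF3 file
#'
#' Returns only rows of type `gene`, as 1-based inclusive intervals sorted by
#' (`seq_name`, `start`). Rows without an `ID` attribute get a synthesized
#' `gene_id` of the form `gene_<seq>_<start>_<end>` with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `seq_name`, `start`, `end`.
#' @export
read_gene_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID)
         else rep(NA_character_, length(gr))
  missing_id <- is.na(ids) | !nzchar(ids)
  if (any(missing_id)) {
    warn(sprintf("%d gene row(s) lack an ID attribute; synthesized ids",
                 sum(missing_id)))
    ids[missing_id] <- sprintf(
      "gene_%s_%d_%d",
      as.character(GenomicRanges::seqnames(gr))[missing_id],
      GenomicRanges::start(gr)[missing_id],
      GenomicRanges::end(gr)[missing_id]
    )
  }
  out <- tibble(
    gene_id = ids,
    seq_name = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
  arrange(out, .data$seq_name, .data$start)
}

#' Read a per-base coverage table
#'
#' Reads the tab-delimited coverage dialect written by [write_coverage_table()]
#' and the `coverage` subcommand: a `#seq  pos  A  C  G  T` header line then
#' one row per covered position (1-based). Positions absent from the table
#' have zero coverage by convention.
#'
#' @param path Path to a coverage TSV.
#' @return A tibble with columns `seq_name`, `pos`, `A`, `C`, `G`, `T`.
#' @export
read_coverage_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(seq_name = character(), pos = integer(),
                  A = integer(), C = integer(), G = integer(), T = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 6L)) {
    abort(sprintf("coverage table %s: expected 6 tab-separated columns", path))
  }
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  counts <- suppressWarnings(matrix(as.numeric(m[, 2:6]), ncol = 5L))
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    abort(sprintf("coverage table %s: positions and counts must be non-negative integers",
                  path))
  }
  out <- tibble(
    seq_name = m[, 1L],
    pos = as.integer(counts[, 1L]),
    A = as.integer(counts[, 2L]),
    C = as.integer(counts[, 3L]),
    G = as.integer(counts[, 4L]),
    T = as.integer(counts[, 5L])
  )
  if (anyDuplicated(paste(out$seq_name, out$pos))) {
    abort(sprintf("coverage table %s: duplicate position rows", path))
  }
  arrange(out, .data$seq_name, .data$pos)
}

#' Write a per-base coverage table
#'
#' @param cov A coverage tibble (`seq_name`, `pos`, `A`, `C`, `G`, `T`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_coverage_table <- function(cov, path) {
  lines <- c(
    "#seq\tpos\tA\tC\tG\tT",
    sprintf("%s\t%d\t%d\t%d\t%d\t%d",
            cov$seq_name, cov$pos, cov$A, cov$C, cov$G, cov$T)
  )
  writeLines(lines, path)
  invisible(path)
}

# Biostrings letter codes -> 1:4 for A/C/G/T, NA otherwise
.biostrings_code_map <- local({
  map <- rep(NA_integer_, 127L)
  map[c(1L, 2L, 4L, 8L)] <- 1:4
  map
})

#' Filter read alignments and fuse mate pairs into fragments
#'
#' Applies the alignment-level filters used throughout: reads with mapping
#' quality `<= mapq_min` are removed; for paired data, pairs with only one
#' aligned mate and pairs whose mates map to different genes are removed;
#' reads overlapping no gene interval are dropped. Surviving mates are fused
#' into a single fragment covering both mates' aligned reference positions
#' (per CIGAR: insertions contribute nothing, deletions and reference skips
#' leave positions uncovered). Where overlapping mates disagree on a base,
#' that position is treated as uncovered in the fragment.
#'
#' @param alignments Path to a position-sorted SAM or BAM file.
#' @param genes Gene intervals tibble from [read_gene_intervals()] (or a
#'   `reference_build`'s `genes` element). Intervals must not overlap.
#' @param mapq_min Reads with MAPQ less than or equal to this are removed.
#'   Default 20 (so MAPQ 21 is the lowest kept).
#' @param min_base_quality Bases below this Phred base quality contribute
#'   nothing (0 disables the check). Default 0.
#'
#' @return A long tibble of fragment bases with columns `fragment_id`
#'   (integer), `gene_id`, `seq_name`, `pos`, `base`, one row per covered
#'   reference position per fragment. Filtering counts are attached as
#'   attribute `counts`.
#' @export
filter_alignments <- function(alignments, genes, mapq_min = 20,
                              min_base_quality = 0) {
  path <- alignments
  if (is_scalar_string(path) && grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  ga <- GenomicAlignments::readGAlignments(Rsamtools::BamFile(path),
                                           param = param)
  meta <- S4Vectors::mcols(ga)
  n_total <- length(ga)

  mapq <- meta$mapq
  keep_mapq <- is.na(mapq) | mapq > mapq_min
  n_mapq_dropped <- sum(!keep_mapq)
  ga <- ga[keep_mapq]
  meta <- S4Vectors::mcols(ga)

  genes_gr <- GenomicRanges::GRanges(
    seqnames = genes$seq_name,
    ranges = IRanges::IRanges(genes$start, genes$end)
  )
  gene_hit <- GenomicRanges::findOverlaps(
    GenomicRanges::granges(ga), genes_gr, type = "within", select = "first"
  )
  n_no_gene <- sum(is.na(gene_hit))
  in_gene <- !is.na(gene_hit)
  ga <- ga[in_gene]
  meta <- S4Vectors::mcols(ga)
  gene_idx <- gene_hit[in_gene]

  paired <- bitwAnd(meta$flag, 1L) > 0L
  qname <- meta$qname
  n_pair_dropped <- 0L
  if (any(paired)) {
    pr <- data.table::data.table(i = which(paired),
                                 qname = qname[paired],
                                 gene = gene_idx[paired])
    grp <- pr[, list(n = .N, ngene = data.table::uniqueN(gene)), by = "qname"]
    ok <- grp[grp$n == 2L & grp$ngene == 1L, ]
    bad_reads <- pr[!pr$qname %in% ok$qname, ]
    n_pair_dropped <- nrow(bad_reads)
    keep <- rep(TRUE, length(ga))
    keep[bad_reads$i] <- FALSE
    ga <- ga[keep]
    meta <- S4Vectors::mcols(ga)
    gene_idx <- gene_idx[keep]
    paired <- paired[keep]
    qname <- meta$qname
  }

  counts <- list(
    reads_total = n_total,
    reads_mapq_dropped = n_mapq_dropped,
    reads_no_gene = n_no_gene,
    reads_pair_dropped = n_pair_dropped,
    reads_kept = length(ga)
  )

  if (length(ga) == 0L) {
    out <- tibble(fragment_id = integer(), gene_id = character(),
                  seq_name = character(), pos = integer(), base = character())
    attr(out, "counts") <- counts
    return(out)
  }

  # fragment id: one per qname for paired reads, one per read otherwise
  frag_key <- ifelse(paired, paste0("p:", qname),
                     paste0("s:", seq_along(ga)))
  frag_id <- match(frag_key, unique(frag_key))

  # lay query sequences onto reference space, then flatten to a long table
  lay <- GenomicAlignments::sequenceLayer(meta$seq,
                                          GenomicAlignments::cigar(ga))
  w <- Biostrings::width(lay)
  pos <- rep(GenomicAlignments::start(ga), w) + sequence(w) - 1L
  codes <- .biostrings_code_map[as.integer(BiocGenerics::unlist(lay))]

  if (min_base_quality > 0) {
    qlay <- GenomicAlignments::sequenceLayer(
      Biostrings::BStringSet(meta$qual), GenomicAlignments::cigar(ga),
      D.letter = "!", N.letter = "!"
    )
    quals <- as.integer(BiocGenerics::unlist(qlay)) - 33L
    codes[quals < min_base_quality] <- NA_integer_
  }

  dt <- data.table::data.table(
    frag = rep(frag_id, w),
    gi = rep(gene_idx, w),
    pos = pos,
    base = codes
  )
  dt <- dt[!is.na(dt$base), ]
  dt <- fuse_mate_bases(dt)

  out <- tibble(
    fragment_id = dt$frag,
    gene_id = genes$gene_id[dt$gi],
    seq_name = genes$seq_name[dt$gi],
    pos = dt$pos,
    base = DNA_BASES[dt$base]
  )
  attr(out, "counts") <- counts
  out
}

# fuse mates within a fragment: positions covered by both mates collapse to
# one row when the bases agree and are dropped entirely when they disagree
fuse_mate_bases <- function(dt) {
  if (nrow(dt) == 0L) return(dt)
  data.table::setkeyv(dt, c("frag", "pos"))
  nr <- nrow(dt)
  dup_next <- c(dt$frag[-1L] == dt$frag[-nr] & dt$pos[-1L] == dt$pos[-nr],
                FALSE)
  dup_prev <- c(FALSE, dup_next[-nr])
  conflict <- dup_next & c(dt$base[-1L] != dt$base[-nr], FALSE)
  drop <- dup_prev | conflict | c(FALSE, conflict[-nr])
  dt[!drop, ]
}

#' Write per-subgenome call files
#'
#' Writes the subgenome call table as one VCF and/or one tab-delimited file
#' per subgenome. Only positions where at least one subgenome has an
#' assigned base are reported. In the VCF, ALT is the assigned base when it
#' differs from REF and `.` otherwise, and the INFO field carries the
#' assigned base (`AB`), the diploid profile code (`DIP`) and the fully
#' characterized flag (`FC`). The tab file has columns `seq_name`,
#' `position`, `ref_base`, `diploid_code`, `assigned_base` (`.` when this
#' subgenome has no call) and `yes`/`no` for fully characterized.
#'
#' @param calls A subgenome call table (see [assign_bases_to_subgenomes()]).
#' @param out_dir Output directory (created if needed).
#' @param format One of `"both"`, `"vcf"`, `"tab"`.
#' @param header Add a header line to the tab files. Default `FALSE`.
#'
#' @return Invisibly, a character vector of written file paths.
#' @export
write_outputs <- function(calls, out_dir, format = c("both", "vcf", "tab"),
                          header = FALSE) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reported <- calls |>
    group_by(.data$seq_name, .data$pos) |>
    filter(any(!is.na(.data$assigned_base))) |>
    ungroup()
  paths <- character(0)
  for (s in unique(calls$subgenome)) {
    sub <- arrange(filter(reported, .data$subgenome == s),
                   .data$seq_name, .data$pos)
    ab <- ifelse(is.na(sub$assigned_base), ".", sub$assigned_base)
    fc <- ifelse(sub$fully_characterized, "yes", "no")
    if (format %in% c("both", "tab")) {
      p <- file.path(out_dir, paste0(s, ".tab"))
      lines <- sprintf("%s\t%d\t%s\t%s\t%s\t%s", sub$seq_name, sub$pos,
                       sub$ref_base, sub$diploid_code, ab, fc)
      if (header) {
        lines <- c("#seq\tposition\tref_base\tdiploid_code\tassigned_base\tfully_characterized",
                   lines)
      }
      writeLines(lines, p)
      paths <- c(paths, p)
    }
    if (format %in% c("both", "vcf")) {
      p <- file.path(out_dir, paste0(s, ".vcf"))
      alt <- ifelse(is.na(sub$assigned_base) |
                      sub$assigned_base == sub$ref_base, ".",
                    sub$assigned_base)
      hdr <- c(
        "##fileformat=VCFv4.2",
        sprintf("##source=homeallele %s",
                as.character(utils::packageVersion("homeallele"))),
        sprintf("##subgenome=%s", s),
        "##INFO=<ID=AB,Number=1,Type=String,Description=\"Assigned base for this subgenome\">",
        "##INFO=<ID=DIP,Number=1,Type=String,Description=\"Diploid progenitor base code\">",
        "##INFO=<ID=FC,Number=1,Type=String,Description=\"Position fully characterized (yes/no)\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
      )
      body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tAB=%s;DIP=%s;FC=%s",
                      sub$seq_name, sub$pos, sub$ref_base, alt, ab,
                      sub$diploid_code, fc)
      writeLines(c(hdr, body), p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Read per-subgenome tab call files back into a call table
#'
#' Inverse of the tab-format side of [write_outputs()].
#'
#' @param paths Named character vector of tab file paths; names are the
#'   subgenome labels.
#' @return A subgenome call table tibble.
#' @export
read_calls_tab <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    abort("`paths` must be named by subgenome label")
  }
  rows <- purrr::imap(paths, function(p, s) {
    lines <- readLines(p)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (length(lines) == 0L) {
      return(tibble(seq_name = character(), pos = integer(),
                    ref_base = character(), subgenome = character(),
                    diploid_code = character(), assigned_base = character(),
                    fully_characterized = logical()))
    }
    m <- matrix(unlist(strsplit(lines, "\t", fixed = TRUE)),
                ncol = 6L, byrow = TRUE)
    tibble(
      seq_name = m[, 1L],
      pos = as.integer(m[, 2L]),
      ref_base = m[, 3L],
      subgenome = s,
      diploid_code = m[, 4L],
      assigned_base = ifelse(m[, 5L] == ".", NA_character_, m[, 5L]),
      fully_characterized = m[, 6L] == "yes"
    )
  })
  arrange(bind_rows(rows), .data$seq_name, .data$pos, .data$subgenome)
}
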