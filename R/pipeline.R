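# End-to-end orchestration: ingestion -> validation -> the six
# base-characterization steps -> output files.

maybe_read <- function(x, reader) {
  if (is_scalar_string(x)) reader(x) else x
}

#' Run the full homoeallelic base-assignment pipeline
#'
#' Executes the whole method: alignment filtering, optional HSP/SBS
#' validation against coverage, HSP discovery at diploid SBS and extra
#' positions, diploid profile construction, base-pattern extraction,
#' noise/embedded filtering, optional overlap merging, pattern-to-subgenome
#' assignment, the per-position base election, and finalization. Every
#' input can be given as a file path (SAM/BAM, VCF, GFF3, TSV) or as the
#' corresponding tibble.
#'
#' @param alignments Position-sorted SAM/BAM path of polyploid reads, or a
#'   fragment tibble from [filter_alignments()].
#' @param hsp Candidate HSP VCF path or tibble from [read_hsp_vcf()].
#' @param genes GFF3 path or gene intervals tibble.
#' @param sbs Named list (one entry per available diploid progenitor,
#'   names = subgenome labels) of SBS VCF paths or tibbles.
#' @param missing Optional label of the single subgenome whose diploid
#'   progenitor has no data.
#' @param poly_coverage Optional polyploid coverage table (path or tibble);
#'   enables HSP validation and discovery.
#' @param dip_coverage Optional named list of diploid coverage tables.
#' @param extra_positions Optional extra-positions list (path or tibble) to
#'   check for HSPs.
#' @param preprocess A [preprocess_config()].
#' @param core A [core_config()].
#' @param mapq_min Mapping-quality filter passed to [filter_alignments()].
#' @param genotype_rule Passed to [read_hsp_vcf()] when `hsp` is a path.
#' @param out_dir Optional output directory for [write_outputs()].
#' @param format Output format when `out_dir` is given.
#' @param header Add a header line to tab outputs. Default `FALSE`.
#'
#' @return An object of class `homeallele_result`: a list with elements
#'   `calls` (the subgenome call table), `patterns`, `profiles`, `hsps`,
#'   `report` (per-stage counts), `subgenomes`, `missing` and `config`.
#' @export
run_pipeline <- function(alignments, hsp, genes, sbs, missing = NULL,
                         poly_coverage = NULL, dip_coverage = NULL,
                         extra_positions = NULL,
                         preprocess = preprocess_config(),
                         core = core_config(), mapq_min = 20,
                         genotype_rule = TRUE, out_dir = NULL,
                         format = "both", header = FALSE) {
  if (!is.list(sbs) || is.null(names(sbs)) || any(!nzchar(names(sbs)))) {
    abort("`sbs` must be a named list (names are subgenome labels)")
  }
  if (!is.null(missing)) {
    if (length(missing) > 1L) {
      abort("at most one diploid progenitor may be designated missing")
    }
    if (missing %in% names(sbs)) {
      abort(sprintf("missing subgenome '%s' must not also have an SBS list",
                    missing))
    }
  }
  subgenomes <- c(names(sbs), missing)
  if (length(subgenomes) < 2L || length(subgenomes) > 10L) {
    abort(sprintf("between 2 and 10 subgenomes are supported, got %d",
                  length(subgenomes)))
  }

  genes <- maybe_read(genes, read_gene_intervals)
  hsps <- if (is_scalar_string(hsp)) {
    read_hsp_vcf(hsp, genotype_rule = genotype_rule)
  } else hsp
  sbs <- purrr::map(sbs, maybe_read, reader = read_sbs_vcf)
  poly_cov <- maybe_read(poly_coverage, read_coverage_table)
  dip_cov <- purrr::map(dip_coverage %||% list(), maybe_read,
                        reader = read_coverage_table)
  extra <- maybe_read(extra_positions, read_extra_positions)

  fragments <- if (is_scalar_string(alignments)) {
    filter_alignments(alignments, genes, mapq_min = mapq_min)
  } else alignments
  frag_counts <- attr(fragments, "counts") %||% list()

  n_hsps_input <- nrow(hsps)
  hsps <- validate_hsps(hsps, poly_cov, preprocess)
  n_hsps_validated <- nrow(hsps)
  sbs <- purrr::imap(sbs, function(s, lab)
    validate_sbss(s, dip_cov[[lab]], preprocess))
  if (!is.null(poly_cov)) {
    hsps <- discover_additional_hsps(sbs, extra, poly_cov, hsps, preprocess)
  }
  hsps <- hsps[lengths(hsps$observed_bases) >= 2L, ]
  n_hsps_final <- nrow(hsps)

  profiles <- build_diploid_profiles(sbs, dip_cov, hsps, missing, preprocess)

  patterns <- extract_base_patterns(fragments, hsps)
  n_patterns_initial <- nrow(patterns)
  patterns <- filter_rare_basepairs(patterns, hsps, genes, core)
  n_patterns_filtered <- nrow(patterns)
  patterns <- remove_embedded_patterns(patterns)
  n_patterns_embedded <- nrow(patterns)
  merge_on <- core$merge %||% !is.null(missing)
  if (merge_on) patterns <- merge_overlapping_patterns(patterns, core)
  n_patterns_merged <- nrow(patterns)

  patterns <- assign_patterns_to_subgenomes(patterns, profiles, missing, core)
  calls <- assign_bases_to_subgenomes(patterns, hsps, genes, subgenomes,
                                      missing, core)
  patterns <- attr(calls, "patterns")
  attr(calls, "patterns") <- NULL
  calls <- finalize_assignments(calls, patterns, core)

  # attach the diploid profile code of each subgenome at each position
  calls <- left_join(
    calls,
    rename(profiles, diploid_code = "code"),
    by = c("seq_name", "pos", "subgenome")
  )
  calls$diploid_code[is.na(calls$diploid_code)] <- CODE_MISSING
  calls <- calls[, c("seq_name", "pos", "ref_base", "observed_bases",
                     "subgenome", "diploid_code", "assigned_base",
                     "fully_characterized")]
  calls <- arrange(calls, .data$seq_name, .data$pos, .data$subgenome)

  reported <- calls |>
    group_by(.data$seq_name, .data$pos) |>
    summarise(any_call = any(!is.na(.data$assigned_base)),
              fc = all(!is.na(.data$assigned_base)), .groups = "drop")
  report <- tibble(
    stage = c("reads_total", "reads_mapq_dropped", "reads_no_gene",
              "reads_pair_dropped", "reads_kept",
              "hsps_input", "hsps_validated", "hsps_final",
              "patterns_initial", "patterns_after_rare_filter",
              "patterns_after_embedded_removal", "patterns_after_merge",
              "positions_reported", "positions_fully_characterized"),
    count = c(frag_counts$reads_total %||% NA_integer_,
              frag_counts$reads_mapq_dropped %||% NA_integer_,
              frag_counts$reads_no_gene %||% NA_integer_,
              frag_counts$reads_pair_dropped %||% NA_integer_,
              frag_counts$reads_kept %||% NA_integer_,
              n_hsps_input, n_hsps_validated, n_hsps_final,
              n_patterns_initial, n_patterns_filtered, n_patterns_embedded,
              n_patterns_merged,
              sum(reported$any_call), sum(reported$fc & reported$any_call))
  )

  result <- structure(
    list(calls = calls, patterns = patterns, profiles = profiles,
         hsps = hsps, report = report, subgenomes = subgenomes,
         missing = missing,
         config = list(preprocess = preprocess, core = core,
                       mapq_min = mapq_min, merge = merge_on)),
    class = "homeallele_result"
  )
  if (!is.null(out_dir)) {
    write_outputs(calls, out_dir, format = format, header = header)
  }
  result
}

#' @export
print.homeallele_result <- function(x, ...) {
  rep_named <- setNames(x$report$count, x$report$stage)
  cat("<homeallele_result>\n")
  cat(sprintf("  subgenomes: %s%s\n", paste(x$subgenomes, collapse = ", "),
              if (!is.null(x$missing))
                sprintf(" (missing diploid: %s)", x$missing) else ""))
  cat(sprintf("  HSP positions: %d (reported: %d, fully characterized: %d)\n",
              rep_named[["hsps_final"]], rep_named[["positions_reported"]],
              rep_named[["positions_fully_characterized"]]))
  cat(sprintf("  base patterns used: %d\n",
              rep_named[["patterns_after_merge"]]))
  invisible(x)
}
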