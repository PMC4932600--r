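# Optional validation of HSP/SBS lists against coverage, discovery of HSPs
# at diploid SBS and user-supplied positions, and diploid base profiles.

#' Preprocessing configuration
#'
#' Thresholds of the validation step. A polyploid base must be supported by
#' at least `hsp_min_frac` of reads at an HSP position to count as a valid
#' subgenome base; a diploid base must be supported by at least
#' `sbs_min_frac` of reads for the SBS to be retained; diploid positions
#' with fewer than `min_diploid_coverage` reads are flagged low-coverage;
#' diploid positions where two or more bases each reach `ambiguous_min_frac`
#' are flagged ambiguous/heterozygous.
#'
#' @param hsp_min_frac Minimum read fraction for a valid HSP base (default
#'   0.05).
#' @param sbs_min_frac Minimum read fraction supporting a diploid SBS base
#'   (default 0.30).
#' @param min_diploid_coverage Minimum diploid read coverage for a concrete
#'   profile base (default 3).
#' @param ambiguous_min_frac Fraction at which a second base makes a diploid
#'   position ambiguous (default 0.20).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(hsp_min_frac = 0.05, sbs_min_frac = 0.30,
                              min_diploid_coverage = 3,
                              ambiguous_min_frac = 0.20) {
  stopifnot(hsp_min_frac > 0, hsp_min_frac < 1,
            sbs_min_frac > 0, sbs_min_frac < 1,
            min_diploid_coverage >= 0, ambiguous_min_frac > 0)
  structure(
    list(hsp_min_frac = hsp_min_frac, sbs_min_frac = sbs_min_frac,
         min_diploid_coverage = min_diploid_coverage,
         ambiguous_min_frac = ambiguous_min_frac),
    class = "preprocess_config"
  )
}

cov_totals <- function(cov) {
  cov$A + cov$C + cov$G + cov$T
}

# per-row list of bases meeting the fraction rule at each coverage row
qualifying_bases <- function(cov, min_frac) {
  total <- cov_totals(cov)
  counts <- cbind(cov$A, cov$C, cov$G, cov$T)
  keep <- counts + 1e-9 >= min_frac * total & counts > 0
  lapply(seq_len(nrow(cov)), function(i) DNA_BASES[keep[i, ]])
}

#' Validate candidate HSPs against polyploid coverage
#'
#' Reduces the observed base set of every HSP to the bases supported by at
#' least `hsp_min_frac` of the reads at that position (the read totals are
#' taken over A/C/G/T calls), then drops positions left with fewer than two
#' valid bases. Positions absent from the coverage table are dropped and
#' counted. With `cov = NULL` validation is skipped and the records pass
#' through unchanged.
#'
#' @param hsps HSP tibble from [read_hsp_vcf()].
#' @param cov Polyploid coverage tibble, or `NULL` to skip validation.
#' @param cfg A [preprocess_config()].
#' @return The validated HSP tibble, with attribute `n_dropped` (positions
#'   removed) when validation ran.
#' @export
validate_hsps <- function(hsps, cov, cfg = preprocess_config()) {
  if (is.null(cov)) return(hsps)
  joined <- inner_join(hsps, cov, by = c("seq_name", "pos"))
  n_missing <- nrow(hsps) - nrow(joined)
  if (nrow(joined) == 0L) {
    out <- hsps[0, ]
    attr(out, "n_dropped") <- nrow(hsps)
    return(out)
  }
  qual <- qualifying_bases(joined, cfg$hsp_min_frac)
  observed <- map2(joined$observed_bases, qual, intersect)
  keep <- lengths(observed) >= 2L
  out <- joined[keep, c("seq_name", "pos", "ref_base"), drop = FALSE]
  out$observed_bases <- observed[keep]
  out <- as_tibble(out)
  attr(out, "n_dropped") <- n_missing + sum(!keep)
  out
}

#' Validate diploid SBS records against diploid coverage
#'
#' An SBS is retained iff at least `sbs_min_frac` of the diploid reads at
#' its position support the substituted base. Positions absent from the
#' coverage table are dropped and counted. With `cov = NULL` validation is
#' skipped.
#'
#' @param sbss SBS tibble from [read_sbs_vcf()].
#' @param cov Coverage tibble for the same diploid, or `NULL`.
#' @param cfg A [preprocess_config()].
#' @return The validated SBS tibble with attribute `n_dropped`.
#' @export
validate_sbss <- function(sbss, cov, cfg = preprocess_config()) {
  if (is.null(cov)) return(sbss)
  joined <- inner_join(sbss, cov, by = c("seq_name", "pos"))
  n_missing <- nrow(sbss) - nrow(joined)
  if (nrow(joined) == 0L) {
    out <- sbss[0, ]
    attr(out, "n_dropped") <- nrow(sbss)
    return(out)
  }
  counts <- cbind(joined$A, joined$C, joined$G, joined$T)
  supp <- counts[cbind(seq_len(nrow(joined)),
                       match(joined$diploid_base, DNA_BASES))]
  keep <- frac_ge(supp, cfg$sbs_min_frac, cov_totals(joined))
  out <- as_tibble(joined[keep, c("seq_name", "pos", "ref_base",
                                  "diploid_base"), drop = FALSE])
  attr(out, "n_dropped") <- n_missing + sum(!keep)
  out
}

#' Discover additional HSPs at diploid SBS and user-supplied positions
#'
#' Checks every diploid SBS position and every user-supplied extra position
#' that is not already an HSP: its polyploid observed base set is built from
#' the coverage table with the `hsp_min_frac` rule, and the position becomes
#' a new HSP when at least two bases qualify. Candidates with no polyploid
#' coverage are skipped. The result is the union with the existing list,
#' deduplicated by position, so running the discovery twice is a no-op.
#'
#' @param sbs_list Named list of SBS tibbles (one per diploid progenitor).
#' @param extra_positions Optional tibble with `seq_name`, `pos`,
#'   `ref_base` (see [read_extra_positions()]).
#' @param poly_cov Polyploid coverage tibble.
#' @param existing Current HSP tibble.
#' @param cfg A [preprocess_config()].
#' @return The augmented HSP tibble, sorted by position, with attribute
#'   `n_discovered`.
#' @export
discover_additional_hsps <- function(sbs_list, extra_positions = NULL,
                                     poly_cov, existing,
                                     cfg = preprocess_config()) {
  cand_tbls <- purrr::map(unname(sbs_list), function(s)
    s[, c("seq_name", "pos", "ref_base")])
  if (!is.null(extra_positions)) {
    cand_tbls <- c(cand_tbls,
                   list(extra_positions[, c("seq_name", "pos", "ref_base")]))
  }
  cand <- bind_rows(cand_tbls)
  if (nrow(cand) == 0L) {
    attr(existing, "n_discovered") <- 0L
    return(existing)
  }
  cand <- distinct(cand, .data$seq_name, .data$pos, .keep_all = TRUE)
  cand <- anti_join(cand, existing, by = c("seq_name", "pos"))
  cand <- inner_join(cand, poly_cov, by = c("seq_name", "pos"))
  if (nrow(cand) > 0L) {
    qual <- qualifying_bases(cand, cfg$hsp_min_frac)
    keep <- lengths(qual) >= 2L
    new <- as_tibble(cand[keep, c("seq_name", "pos", "ref_base"),
                          drop = FALSE])
    new$observed_bases <- qual[keep]
  } else {
    new <- existing[0, ]
  }
  out <- arrange(bind_rows(existing, new), .data$seq_name, .data$pos)
  attr(out, "n_discovered") <- nrow(new)
  out
}

#' Read an extra-positions list
#'
#' Tab-delimited file with sequence name, 1-based position and reference
#' base, naming positions to be checked for HSPs in addition to the input
#' HSP list.
#'
#' @param path Path to the tab-delimited file (lines starting with `#` are
#'   ignored).
#' @return A tibble with `seq_name`, `pos`, `ref_base`.
#' @export
read_extra_positions <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(seq_name = character(), pos = integer(),
                  ref_base = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    abort(sprintf("extra-positions file %s: expected 3 tab-separated columns",
                  path))
  }
  m <- matrix(unlist(lapply(parts, `[`, 1:3)), ncol = 3L, byrow = TRUE)
  tibble(seq_name = m[, 1L], pos = as.integer(m[, 2L]),
         ref_base = toupper(m[, 3L]))
}

#' Build per-diploid base profiles at HSP positions
#'
#' For every HSP position and every diploid progenitor, determines the
#' diploid's base state: `?` for the designated missing progenitor at every
#' position; otherwise the substituted base when a validated SBS exists
#' there; otherwise, when a coverage table is available, `0` (no coverage)
#' for zero reads, `<` (low coverage) below `min_diploid_coverage` reads,
#' `*` (ambiguous/heterozygous) when no single base dominates, or the
#' majority base; and when no coverage table was supplied, the reference
#' base (an SBS list is defined relative to the reference, so absence of an
#' SBS means the diploid agrees with it).
#'
#' @param sbs_list Named list of validated SBS tibbles, one per available
#'   diploid progenitor. Names are the subgenome labels.
#' @param dip_cov Named list of coverage tibbles (may be missing entries or
#'   `NULL`).
#' @param hsps Final HSP tibble.
#' @param missing Optional label of the single missing diploid progenitor.
#' @param cfg A [preprocess_config()].
#' @return A tibble with columns `subgenome`, `seq_name`, `pos`, `code`
#'   where `code` is one of `A`,`C`,`G`,`T`,`0`,`<`,`*`,`?`.
#' @export
build_diploid_profiles <- function(sbs_list, dip_cov = NULL, hsps,
                                   missing = NULL,
                                   cfg = preprocess_config()) {
  if (!is.null(missing) && length(missing) > 1L) {
    abort("at most one diploid progenitor may be designated missing")
  }
  if (!is.null(missing) && missing %in% names(sbs_list)) {
    abort(sprintf("missing diploid '%s' must not also have an SBS list",
                  missing))
  }
  labels <- c(names(sbs_list), missing)
  positions <- hsps[, c("seq_name", "pos", "ref_base")]
  profiles <- purrr::map(labels, function(lab) {
    out <- tibble(subgenome = lab, seq_name = positions$seq_name,
                  pos = positions$pos, code = NA_character_)
    if (!is.null(missing) && lab == missing) {
      out$code <- CODE_MISSING
      return(out)
    }
    sbs <- sbs_list[[lab]]
    hit <- left_join(positions, sbs[, c("seq_name", "pos", "diploid_base")],
                     by = c("seq_name", "pos"))
    out$code <- hit$diploid_base
    todo <- is.na(out$code)
    cov <- dip_cov[[lab]]
    if (is.null(cov)) {
      out$code[todo] <- positions$ref_base[todo]
      return(out)
    }
    cv <- left_join(positions[todo, ], cov, by = c("seq_name", "pos"))
    counts <- cbind(cv$A, cv$C, cv$G, cv$T)
    counts[is.na(counts)] <- 0L
    total <- rowSums(counts)
    n_ambig <- rowSums(counts + 1e-9 >= cfg$ambiguous_min_frac * total &
                         counts > 0)
    code <- character(nrow(cv))
    code[total == 0] <- CODE_NO_COVERAGE
    low <- total > 0 & total < cfg$min_diploid_coverage
    code[low] <- CODE_LOW_COVERAGE
    rest <- total >= cfg$min_diploid_coverage
    code[rest & n_ambig >= 2] <- CODE_AMBIGUOUS
    maj <- rest & n_ambig < 2
    code[maj] <- DNA_BASES[max.col(counts[maj, , drop = FALSE],
                                   ties.method = "first")]
    out$code[todo] <- code
    out
  })
  bind_rows(profiles)
}
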