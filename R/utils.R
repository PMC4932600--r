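#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join semi_join anti_join bind_rows distinct n rename count
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map2 map2_lgl map2_chr map_chr map_int map_dbl
#'   map_lgl pmap imap imap_chr
#' @importFrom stats rnorm setNames
#' @importFrom utils head tail
NULL

# data.table is used via :: for the large pileup tallies
.datatable.aware <- TRUE

DNA_BASES <- c("A", "C", "G", "T")

# Profile codes beyond the four bases: no coverage, low coverage,
# ambiguous/heterozygous, missing diploid.
CODE_NO_COVERAGE <- "0"
CODE_LOW_COVERAGE <- "<"
CODE_AMBIGUOUS <- "*"
CODE_MISSING <- "?"

# "at least X%" with a tolerance that keeps integer boundary cases exact
# (0.05 * 100 > 5 in binary floating point; the epsilon restores count >= 5).
frac_ge <- function(count, frac, total) {
  count + 1e-9 >= frac * total
}

# percentage comparison with the same epsilon
pct_ge <- function(pct, min_frac) {
  pct + 1e-9 >= 100 * min_frac
}

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

base_to_int <- function(base) {
  match(base, DNA_BASES)
}

# integer code -> base letter; 0 and NA map to NA (no call)
int_to_base <- function(i) {
  out <- rep(NA_character_, length(i))
  ok <- !is.na(i) & i > 0L
  out[ok] <- DNA_BASES[i[ok]]
  out
}

# stable position-set key for a pattern
pattern_key <- function(positions, bases) {
  paste(positions, bases, sep = ":", collapse = ";")
}

assert_positions <- function(df, what = "record") {
  if (!all(c("seq_name", "pos") %in% names(df))) {
    abort(sprintf("%s table must have columns 'seq_name' and 'pos'", what))
  }
  if (any(df$pos < 1L)) abort(sprintf("%s positions must be >= 1", what))
  invisible(df)
}
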