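# Accuracy evaluation against truth, and counting of shared positions and
# shared bases between two call sets (or a call set and a diploid profile).

normalize_call_set <- function(x, what = "call set") {
  if (is.data.frame(x) && "assigned_base" %in% names(x)) {
    out <- tibble(seq_name = x$seq_name, pos = x$pos,
                  subgenome = x$subgenome, base = x$assigned_base)
  } else if (is.data.frame(x) && "code" %in% names(x)) {
    out <- tibble(seq_name = x$seq_name, pos = x$pos,
                  subgenome = x$subgenome, base = x$code)
  } else if (is.data.frame(x) && "base" %in% names(x)) {
    out <- tibble(seq_name = x$seq_name, pos = x$pos,
                  subgenome = x$subgenome, base = x$base)
  } else {
    abort(sprintf("%s must have an 'assigned_base', 'code' or 'base' column",
                  what))
  }
  filter(out, .data$base %in% DNA_BASES)
}

#' Count shared positions and shared bases between two call sets
#'
#' For every requested subgenome pairing, counts the positions at which both
#' call sets carry a concrete base (shared positions) and how many of those
#' agree (shared bases). Either side may be a subgenome call table or a
#' diploid profile, so the comparison covers both subgenome-vs-progenitor
#' and subgenome-vs-subgenome relationships; positions without a concrete
#' base on either side are excluded.
#'
#' @param a,b Subgenome call tables (from [run_pipeline()]'s `calls` or
#'   [read_calls_tab()]) or diploid profile tibbles.
#' @param pairing Named character vector mapping subgenome labels of `a` to
#'   labels of `b`; by default labels common to both are paired with
#'   themselves.
#' @return A tibble of class `homeallele_comparison` with one row per pair:
#'   `subgenome_a`, `subgenome_b`, `shared_positions`, `same_base`.
#' @export
compare_call_sets <- function(a, b, pairing = NULL) {
  ca <- normalize_call_set(a, "`a`")
  cb <- normalize_call_set(b, "`b`")
  if (nrow(ca) > 0L && nrow(cb) > 0L &&
      length(intersect(unique(ca$seq_name), unique(cb$seq_name))) == 0L) {
    abort("call sets share no reference sequence names")
  }
  if (is.null(pairing)) {
    shared <- intersect(unique(ca$subgenome), unique(cb$subgenome))
    pairing <- setNames(shared, shared)
  }
  if (length(pairing) == 0L) abort("no subgenome pairing to compare")
  rows <- purrr::imap(pairing, function(sb, sa) {
    xa <- filter(ca, .data$subgenome == sa)
    xb <- filter(cb, .data$subgenome == sb)
    j <- inner_join(xa, xb, by = c("seq_name", "pos"),
                    suffix = c("_a", "_b"))
    tibble(subgenome_a = sa, subgenome_b = sb,
           shared_positions = nrow(j),
           same_base = sum(j$base_a == j$base_b))
  })
  structure(bind_rows(rows), class = c("homeallele_comparison",
                                       class(tibble())))
}

#' Evaluate call accuracy against known truth
#'
#' Compares assigned bases with a truth table (for simulated data, the
#' simulator's per-subgenome base truth). Each assigned (position,
#' subgenome) pair counts as one assignment, so a fully characterized
#' position contributes once per subgenome.
#'
#' @param calls A subgenome call table.
#' @param truth Tibble with columns `seq_name`, `pos`, `subgenome`, `base`.
#'   Must cover every evaluated assignment.
#' @param fully_characterized_only Evaluate only positions where every
#'   subgenome was assigned a base. Default `TRUE`.
#' @return A one-row tibble with `accuracy` (fraction in `[0,1]`, `NA` when
#'   nothing was evaluable), `n_correct` and `n_evaluated`.
#' @export
evaluate_accuracy <- function(calls, truth, fully_characterized_only = TRUE) {
  ev <- filter(calls, !is.na(.data$assigned_base))
  if (fully_characterized_only && "fully_characterized" %in% names(ev)) {
    ev <- filter(ev, .data$fully_characterized)
  }
  if (nrow(ev) == 0L) {
    inform("no evaluable assignments; accuracy is undefined")
    return(tibble(accuracy = NA_real_, n_correct = 0L, n_evaluated = 0L))
  }
  j <- left_join(ev, truth[, c("seq_name", "pos", "subgenome", "base")],
                 by = c("seq_name", "pos", "subgenome"))
  if (anyNA(j$base)) {
    abort(sprintf("truth does not cover %d evaluated assignment(s)",
                  sum(is.na(j$base))))
  }
  n_correct <- sum(j$assigned_base == j$base)
  tibble(accuracy = n_correct / nrow(j), n_correct = n_correct,
         n_evaluated = nrow(j))
}
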