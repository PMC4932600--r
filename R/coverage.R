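# Per-position, per-base read counts from filtered fragments.

#' Count per-base coverage from filtered fragments
#'
#' Tallies, for every covered reference position, how many fragments support
#' each base. Counting is fragment-level: a read pair contributes at most one
#' count per position, and positions where the two mates disagreed were
#' already dropped when the fragment was built, so they contribute nothing.
#' This keeps pattern support and coverage denominators in the same unit.
#'
#' @param fragments Long fragment-base tibble from [filter_alignments()]
#'   (columns `fragment_id`, `seq_name`, `pos`, `base`).
#' @param restrict_to Optional tibble with `seq_name` and `pos`; when given,
#'   only the requested positions are emitted.
#'
#' @return A coverage tibble (`seq_name`, `pos`, `A`, `C`, `G`, `T`) sorted
#'   by position. Positions with no coverage are absent.
#' @export
compute_base_coverage <- function(fragments, restrict_to = NULL) {
  empty <- tibble(seq_name = character(), pos = integer(),
                  A = integer(), C = integer(), G = integer(), T = integer())
  if (nrow(fragments) == 0L) return(empty)
  dt <- data.table::data.table(
    seq_name = fragments$seq_name,
    pos = fragments$pos,
    b = match(fragments$base, DNA_BASES)
  )
  dt <- dt[!is.na(dt$b), ]
  if (nrow(dt) == 0L) return(empty)
  tall <- dt[, list(n = .N), by = c("seq_name", "pos", "b")]
  wide <- data.table::dcast(tall, seq_name + pos ~ b, value.var = "n",
                            fill = 0L)
  for (k in as.character(1:4)) {
    if (!k %in% names(wide)) wide[[k]] <- 0L
  }
  out <- tibble(
    seq_name = wide$seq_name,
    pos = as.integer(wide$pos),
    A = as.integer(wide[["1"]]),
    C = as.integer(wide[["2"]]),
    G = as.integer(wide[["3"]]),
    T = as.integer(wide[["4"]])
  )
  if (!is.null(restrict_to)) {
    assert_positions(restrict_to, "restrict_to")
    out <- semi_join(out, restrict_to, by = c("seq_name", "pos"))
  }
  arrange(out, .data$seq_name, .data$pos)
}
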