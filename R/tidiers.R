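# broom-style accessors and plots for pipeline results.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pipeline result into its call table
#'
#' @param x A `homeallele_result` from [run_pipeline()].
#' @param ... Unused.
#' @return The subgenome call table: one row per HSP position and
#'   subgenome.
#' @export
tidy.homeallele_result <- function(x, ...) {
  x$calls
}

#' One-row summary of a pipeline result
#'
#' @param x A `homeallele_result`.
#' @param ... Unused.
#' @return A one-row tibble: numbers of HSP positions, reported and fully
#'   characterized positions, assignments, base patterns used and
#'   subgenomes.
#' @export
glance.homeallele_result <- function(x, ...) {
  rep_named <- setNames(x$report$count, x$report$stage)
  tibble(
    n_hsp_positions = rep_named[["hsps_final"]],
    n_positions_reported = rep_named[["positions_reported"]],
    n_fully_characterized = rep_named[["positions_fully_characterized"]],
    prop_fully_characterized =
      rep_named[["positions_fully_characterized"]] /
        max(1L, rep_named[["positions_reported"]]),
    n_assignments = sum(!is.na(x$calls$assigned_base)),
    n_patterns = rep_named[["patterns_after_merge"]],
    n_subgenomes = length(x$subgenomes)
  )
}

#' Plot per-subgenome assignment counts
#'
#' Bar chart of assigned positions per subgenome, split by whether the
#' position is fully characterized -- the quick look at how much of the HSP
#' landscape each subgenome resolved.
#'
#' @param object A `homeallele_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.homeallele_result <- function(object, ...) {
  df <- object$calls |>
    filter(!is.na(.data$assigned_base)) |>
    count(.data$subgenome, .data$fully_characterized)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subgenome, y = .data$n,
                                   fill = .data$fully_characterized)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "subgenome", y = "assigned HSP positions",
                  fill = "fully\ncharacterized") +
    ggplot2::theme_minimal()
}

#' @export
glance.homeallele_comparison <- function(x, ...) {
  tibble(
    shared_positions = sum(x$shared_positions),
    same_base = sum(x$same_base),
    prop_same = sum(x$same_base) / max(1L, sum(x$shared_positions))
  )
}

#' Plot agreement between two call sets
#'
#' @param object A `homeallele_comparison` from [compare_call_sets()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.homeallele_comparison <- function(object, ...) {
  df <- mutate(as_tibble(object),
               pair = paste(.data$subgenome_a, .data$subgenome_b,
                            sep = " vs "),
               prop = .data$same_base / pmax(1L, .data$shared_positions))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$prop)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "shared bases / shared positions") +
    ggplot2::theme_minimal()
}
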