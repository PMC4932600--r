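# Subgenome assignment: diploid-identity scoring of base patterns, the
# per-position base election (maximum or additive mode), and finalization by
# elimination plus recheck of leftover patterns.

#' Core algorithm configuration
#'
#' Tunable parameters of the base-characterization steps. Defaults are the
#' method's standard values: 5% for the rare base-pair filter, 50% minimum
#' diploid identity for pattern assignment, maximum mode for the base
#' election, finalization on, and overlap merging enabled exactly when a
#' diploid progenitor is missing.
#'
#' @param basepair_min_frac Minimum read fraction of a base combination at
#'   two consecutive HSP positions (default 0.05).
#' @param identity_min Minimum fractional identity with a diploid for a
#'   pattern to be assigned to its subgenome (default 0.50).
#' @param mode Base election mode, `"max"` (base from the single
#'   best-scoring pattern) or `"additive"` (base with the highest summed
#'   score across patterns containing it).
#' @param merge `TRUE`/`FALSE` to force overlap merging on or off, or `NULL`
#'   (default) for the automatic rule: on iff a diploid is missing.
#' @param finalize Run the finalization step (default `TRUE`). Turn off for
#'   heterozygous species, where elimination can mistake allelic variation
#'   for a homeologous base.
#' @param min_overlap Minimum number of shared positions for two patterns
#'   to merge (default 1; raise for higher ploidies where single-position
#'   overlaps can chain chimeric merges).
#' @param max_iterations Safety cap on the election and finalization loops
#'   (default 100).
#' @return A list of class `core_config`.
#' @export
core_config <- function(basepair_min_frac = 0.05, identity_min = 0.50,
                        mode = c("max", "additive"), merge = NULL,
                        finalize = TRUE, min_overlap = 1,
                        max_iterations = 100) {
  mode <- match.arg(mode)
  stopifnot(basepair_min_frac > 0, basepair_min_frac < 1,
            identity_min > 0, identity_min < 1, min_overlap >= 1)
  structure(
    list(basepair_min_frac = basepair_min_frac, identity_min = identity_min,
         mode = mode, merge = merge, finalize = finalize,
         min_overlap = as.integer(min_overlap),
         max_iterations = as.integer(max_iterations)),
    class = "core_config"
  )
}

TIE_EPS <- 1e-9

#' Assign base patterns to subgenomes by diploid identity
#'
#' For every pattern and every diploid profile, the percentage identity is
#' the share of the pattern's positions, among those where the profile has a
#' concrete base (`A`/`C`/`G`/`T`), at which the pattern matches the
#' diploid; it is undefined when no position is informative. A pattern is
#' assigned to every subgenome whose identity reaches `identity_min` (a
#' pattern may satisfy the rule for several subgenomes; the per-position
#' election arbitrates). When a diploid progenitor is missing, a pattern
#' assigned to no subgenome is assigned to the missing one -- it must come
#' from some subgenome of the polyploid, and low identity with every known
#' diploid is evidence for the one without data.
#'
#' @param patterns Pattern tibble.
#' @param profiles Diploid profile tibble from [build_diploid_profiles()].
#' @param missing Optional missing-subgenome label.
#' @param cfg A [core_config()].
#' @return The pattern tibble with list-columns `identity` (named numeric,
#'   `NA` = undefined) and `assigned_to` (character vector of subgenome
#'   labels).
#' @export
assign_patterns_to_subgenomes <- function(patterns, profiles, missing = NULL,
                                          cfg = core_config()) {
  subgenomes <- unique(profiles$subgenome)
  if (!is.null(missing) && !missing %in% subgenomes) {
    abort(sprintf("missing label '%s' has no profile", missing))
  }
  if (nrow(patterns) == 0L) {
    patterns$identity <- list()
    patterns$assigned_to <- list()
    return(patterns)
  }
  out <- patterns |>
    dplyr::group_split(.data$gene_id) |>
    purrr::map(function(sub) {
      ps <- sort(unique(unlist(sub$positions)))
      sq <- sub$seq_name[1L]
      n <- nrow(sub)
      M <- pattern_matrix(sub, ps)
      ident <- matrix(NA_real_, n, length(subgenomes),
                      dimnames = list(NULL, subgenomes))
      for (s in subgenomes) {
        pr <- profiles[profiles$subgenome == s & profiles$seq_name == sq, ]
        code <- pr$code[match(ps, pr$pos)]
        prof_int <- base_to_int(code)  # NA for 0/</*/? and unknown positions
        B <- matrix(prof_int, n, length(ps), byrow = TRUE)
        informative <- (M > 0L) & !is.na(B)
        n_inf <- rowSums(informative)
        n_match <- rowSums(informative & (M == B))
        ident[, s] <- ifelse(n_inf > 0L, 100 * n_match / n_inf, NA_real_)
      }
      sub$identity <- lapply(seq_len(n), function(i) ident[i, ])
      sub$assigned_to <- lapply(seq_len(n), function(i) {
        a <- subgenomes[!is.na(ident[i, ]) &
                          pct_ge(ident[i, ], cfg$identity_min)]
        if (length(a) == 0L && !is.null(missing)) a <- missing
        a
      })
      sub
    }) |>
    bind_rows()
  out
}

# per-pattern election score for each subgenome; for the missing subgenome
# the score is 100 minus the best identity with any present diploid
# ("least like any known diploid"), falling back to read support when no
# identity is defined at all
election_scores <- function(ident, support, subgenomes, missing) {
  sc <- ident
  if (!is.null(missing)) {
    present <- setdiff(subgenomes, missing)
    if (length(present)) {
      pm <- ident[, present, drop = FALSE]
      rmax <- apply(pm, 1L, function(r)
        if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
      sc[, missing] <- ifelse(is.na(rmax), support, 100 - rmax)
    } else {
      sc[, missing] <- support
    }
  }
  sc
}

# elect a base among candidate rows at one (position, subgenome) cell;
# returns an integer base code, 0 for no call (no candidate or a tie)
elect_base <- function(bases, scores, mode) {
  if (length(bases) == 0L) return(0L)
  if (mode == "max") {
    mx <- max(scores)
    winners <- unique(bases[scores >= mx - TIE_EPS])
    if (length(winners) == 1L) winners else 0L
  } else {
    sums <- tapply(scores, bases, sum)
    mx <- max(sums)
    winners <- as.integer(names(sums))[sums >= mx - TIE_EPS]
    if (length(winners) == 1L) winners else 0L
  }
}

#' Assign bases to subgenomes from assigned patterns
#'
#' The per-position election. For every HSP position and subgenome, the
#' candidate bases are those carried at that position by active patterns
#' assigned to the subgenome (restricted to the position's validated
#' observed set). In maximum mode the base of the best-scoring pattern wins;
#' in additive mode the base with the highest summed score across patterns
#' containing it wins; an exact tie yields no call. After each pass, active
#' patterns that conflict with an elected base of a subgenome they are
#' assigned to are removed; passes then re-elect the still-open cells
#' (elected bases are never retracted) and repeat until no more bases can
#' be assigned and no more patterns are removed. Removing a conflicting
#' pattern can break an earlier tie, which is why the loop continues after
#' removals.
#'
#' @param patterns Pattern tibble carrying `identity` and `assigned_to`
#'   (from [assign_patterns_to_subgenomes()]).
#' @param hsps Validated HSP tibble.
#' @param genes Gene intervals tibble.
#' @param subgenomes Character vector of all subgenome labels.
#' @param missing Optional missing-subgenome label.
#' @param cfg A [core_config()].
#' @return A subgenome call table: a long tibble with one row per HSP
#'   position and subgenome (`seq_name`, `pos`, `ref_base`,
#'   `observed_bases`, `subgenome`, `assigned_base`, `fully_characterized`).
#'   The updated pattern tibble (with removal states) is attached as
#'   attribute `patterns`.
#' @export
assign_bases_to_subgenomes <- function(patterns, hsps, genes, subgenomes,
                                       missing = NULL, cfg = core_config()) {
  hsp_gene <- gene_of_positions(hsps$seq_name, hsps$pos, genes)
  hsps_in <- hsps[!is.na(hsp_gene), ]
  gene_of_hsp <- hsp_gene[!is.na(hsp_gene)]
  S <- length(subgenomes)

  calls_rows <- list()
  pattern_states <- list()
  for (g in unique(gene_of_hsp)) {
    hs <- hsps_in[gene_of_hsp == g, ]
    hs <- hs[order(hs$pos), ]
    ps <- hs$pos
    m <- length(ps)
    sub <- patterns[patterns$gene_id == g & patterns$state != "removed", ]
    sub_removed <- patterns[patterns$gene_id == g &
                              patterns$state == "removed", ]
    n <- nrow(sub)
    calls <- matrix(0L, m, S, dimnames = list(NULL, subgenomes))
    if (n > 0L) {
      M <- pattern_matrix(sub, ps)
      ident <- do.call(rbind, sub$identity)
      ident <- ident[, subgenomes, drop = FALSE]
      sc <- election_scores(ident, sub$support, subgenomes, missing)
      assigned <- vapply(subgenomes, function(s)
        map_lgl(sub$assigned_to, function(a) s %in% a), logical(n))
      assigned <- matrix(assigned, nrow = n,
                         dimnames = list(NULL, subgenomes))
      obs_int <- lapply(hs$observed_bases, base_to_int)
      active <- rep(TRUE, n)
      iter <- 0L
      repeat {
        iter <- iter + 1L
        if (iter > cfg$max_iterations) {
          abort("base election did not converge within max_iterations")
        }
        # elect only still-open cells: calls accumulate and are never
        # retracted, so passes continue until no more bases can be assigned
        changed <- FALSE
        for (s_i in seq_len(S)) {
          cand_rows <- which(active & assigned[, s_i])
          if (length(cand_rows) == 0L) next
          for (j in which(calls[, s_i] == 0L)) {
            rows <- cand_rows[M[cand_rows, j] > 0L &
                                M[cand_rows, j] %in% obs_int[[j]]]
            b <- elect_base(M[rows, j], sc[rows, s_i], cfg$mode)
            if (b > 0L) { calls[j, s_i] <- b; changed <- TRUE }
          }
        }
        # drop patterns conflicting with an elected base of their subgenome
        removed_any <- FALSE
        for (i in which(active)) {
          for (s_i in which(assigned[i, ])) {
            jj <- which(M[i, ] > 0L & calls[, s_i] > 0L &
                          M[i, ] != calls[, s_i])
            if (length(jj)) {
              active[i] <- FALSE
              removed_any <- TRUE
              break
            }
          }
        }
        if (!changed && !removed_any) break
      }
      sub$state[!active] <- "removed"
    }
    pattern_states[[g]] <- bind_rows(sub, sub_removed)
    calls_rows[[g]] <- tibble(
      seq_name = rep(hs$seq_name, each = S),
      pos = rep(ps, each = S),
      ref_base = rep(hs$ref_base, each = S),
      observed_bases = rep(hs$observed_bases, each = S),
      subgenome = rep(subgenomes, m),
      assigned_base = int_to_base(as.vector(t(calls)))
    )
  }
  out <- bind_rows(calls_rows)
  if (nrow(out) == 0L) {
    out <- tibble(seq_name = character(), pos = integer(),
                  ref_base = character(), observed_bases = list(),
                  subgenome = character(), assigned_base = character())
  }
  out <- set_fully_characterized(out)
  attr(out, "patterns") <- if (length(pattern_states)) {
    renumber_patterns(bind_rows(pattern_states))
  } else {
    patterns
  }
  out
}

set_fully_characterized <- function(calls) {
  calls |>
    group_by(.data$seq_name, .data$pos) |>
    mutate(fully_characterized = all(!is.na(.data$assigned_base))) |>
    ungroup()
}

#' Finalize base assignments
#'
#' Two closing rules applied to a fixed point. Elimination: every base at an
#' HSP position must belong to some subgenome, so when exactly one observed
#' base is still unassigned and exactly one subgenome lacks a call, that
#' base goes to that subgenome. Recheck: patterns that were never assigned
#' (undefined or low diploid identity) or were removed as conflicting are
#' re-scored against the already assigned bases (identity over the
#' pattern's positions that have a call for the subgenome) and, where they
#' reach `identity_min`, fed as candidates into the election for positions
#' that still lack a call; existing calls are never retracted. Elimination
#' can mis-assign where a subgenome carries allelic (within-subgenome)
#' variation, so the whole step can be disabled via `core_config(finalize =
#' FALSE)`.
#'
#' @param calls Subgenome call table from [assign_bases_to_subgenomes()].
#' @param patterns Pattern tibble including removed/unassigned patterns.
#' @param cfg A [core_config()].
#' @return The finalized call table with updated `fully_characterized`.
#' @export
finalize_assignments <- function(calls, patterns, cfg = core_config()) {
  if (!cfg$finalize || nrow(calls) == 0L) return(calls)
  subgenomes <- unique(calls$subgenome)
  S <- length(subgenomes)

  out <- calls |>
    dplyr::group_split(.data$seq_name) |>
    purrr::map(function(cl) {
      sq <- cl$seq_name[1L]
      pos_tbl <- distinct(cl[, c("pos", "ref_base")])
      ps <- sort(pos_tbl$pos)
      m <- length(ps)
      obs <- cl$observed_bases[match(ps, cl$pos)]
      obs_int <- lapply(obs, base_to_int)
      cm <- matrix(0L, m, S, dimnames = list(NULL, subgenomes))
      idx <- cbind(match(cl$pos, ps), match(cl$subgenome, subgenomes))
      cm[idx] <- ifelse(is.na(cl$assigned_base), 0L,
                        base_to_int(cl$assigned_base))
      lp <- patterns[patterns$seq_name == sq &
                       (patterns$state == "removed" |
                          lengths(patterns$assigned_to) == 0L), ]
      LM <- if (nrow(lp) > 0L) pattern_matrix(lp, ps) else NULL

      iter <- 0L
      repeat {
        iter <- iter + 1L
        if (iter > cfg$max_iterations) {
          abort("finalization did not converge within max_iterations")
        }
        changed <- FALSE
        # (a) elimination
        for (j in seq_len(m)) {
          unassigned <- setdiff(obs_int[[j]], cm[j, ])
          open <- which(cm[j, ] == 0L)
          if (length(unassigned) == 1L && length(open) == 1L) {
            cm[j, open] <- unassigned
            changed <- TRUE
          }
        }
        # (b) recheck leftover patterns against the assigned bases
        if (!is.null(LM) && nrow(LM) > 0L) {
          for (s_i in seq_len(S)) {
            called <- cm[, s_i] > 0L
            if (!any(called)) next
            Bcall <- matrix(cm[, s_i], nrow(LM), m, byrow = TRUE)
            informative <- (LM > 0L) & rep(called, each = nrow(LM))
            n_inf <- rowSums(informative)
            n_match <- rowSums(informative & (LM == Bcall))
            rid <- 100 * n_match / pmax(n_inf, 1L)
            ok <- n_inf > 0L & pct_ge(rid, cfg$identity_min)
            if (!any(ok)) next
            for (j in which(cm[, s_i] == 0L)) {
              rows <- which(ok & LM[, j] > 0L &
                              LM[, j] %in% obs_int[[j]])
              b <- elect_base(LM[rows, j], rid[rows], cfg$mode)
              if (b > 0L) { cm[j, s_i] <- b; changed <- TRUE }
            }
          }
        }
        if (!changed) break
      }
      cl$assigned_base <- int_to_base(cm[idx])
      cl
    }) |>
    bind_rows()
  set_fully_characterized(out)
}
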