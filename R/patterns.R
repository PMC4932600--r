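# Base-pattern machinery: extraction from fragments, noise filtering,
# embedded-pattern removal, and iterative overlap merging.
#
# Internally each gene's patterns are held as an n x m integer matrix over
# the gene's ordered HSP positions (0 = position not covered, 1..4 = ACGT),
# which makes the pairwise overlap/compatibility computations a handful of
# matrix products.

new_pattern_tbl <- function(gene_id = character(), seq_name = character(),
                            positions = list(), bases = list(),
                            support = integer(), state = character()) {
  tibble(
    pattern_id = seq_along(gene_id),
    gene_id = gene_id,
    seq_name = seq_name,
    positions = positions,
    bases = bases,
    size = lengths(positions),
    support = as.integer(support),
    state = if (length(state)) state else rep("active", length(gene_id))
  )
}

renumber_patterns <- function(patterns) {
  patterns$pattern_id <- seq_len(nrow(patterns))
  patterns$size <- lengths(patterns$positions)
  patterns
}

# n x m integer base matrix for one gene's patterns over positions `ps`
pattern_matrix <- function(patterns, ps) {
  n <- nrow(patterns)
  M <- matrix(0L, nrow = n, ncol = length(ps))
  for (i in seq_len(n)) {
    j <- match(patterns$positions[[i]], ps)
    ok <- !is.na(j)
    M[i, j[ok]] <- base_to_int(patterns$bases[[i]])[ok]
  }
  M
}

# pairwise shared-position and agreeing-position counts
pattern_pairwise <- function(M) {
  covered <- (M > 0) * 1L
  shared <- covered %*% t(covered)
  matches <- matrix(0L, nrow(M), nrow(M))
  for (b in 1:4) {
    Ab <- (M == b) * 1L
    matches <- matches + Ab %*% t(Ab)
  }
  list(shared = shared, matches = matches)
}

matrix_to_pattern_rows <- function(M, support, state, gene_id, seq_name, ps) {
  keep <- which(rowSums(M > 0) > 0)
  tibble(
    pattern_id = NA_integer_,
    gene_id = gene_id,
    seq_name = seq_name,
    positions = lapply(keep, function(i) ps[M[i, ] > 0]),
    bases = lapply(keep, function(i) int_to_base(M[i, M[i, ] > 0])),
    size = vapply(keep, function(i) sum(M[i, ] > 0), integer(1)),
    support = as.integer(support[keep]),
    state = state[keep]
  )
}

#' Extract base patterns from fragments
#'
#' A base pattern is the ordered sequence of (position, base) pairs over the
#' HSP positions covered by one fragment (a read pair, or a single read for
#' single-end data). Fragments covering no HSP position contribute nothing;
#' identical patterns within a gene are collapsed and their read support
#' summed.
#'
#' @param fragments Long fragment-base tibble from [filter_alignments()].
#' @param hsps Validated HSP tibble.
#' @return A pattern tibble with columns `pattern_id`, `gene_id`,
#'   `seq_name`, list-columns `positions` and `bases`, `size`, `support`
#'   and `state` (all `"active"`).
#' @export
extract_base_patterns <- function(fragments, hsps) {
  hits <- inner_join(fragments,
                     hsps[, c("seq_name", "pos")],
                     by = c("seq_name", "pos"))
  hits <- hits[hits$base %in% DNA_BASES, ]  # N etc. contribute nothing
  if (nrow(hits) == 0L) return(new_pattern_tbl())
  dt <- data.table::as.data.table(hits)
  data.table::setorderv(dt, c("fragment_id", "pos"))
  grp <- dt[, list(gene_id = gene_id[1L], seq_name = seq_name[1L],
                   key = paste(pos, base, sep = ":", collapse = ";")),
            by = "fragment_id"]
  cnt <- grp[, list(support = .N), by = c("gene_id", "seq_name", "key")]
  pairs <- strsplit(cnt$key, ";", fixed = TRUE)
  positions <- lapply(pairs, function(p)
    as.integer(sub(":.*", "", p)))
  bases <- lapply(pairs, function(p) sub(".*:", "", p))
  out <- new_pattern_tbl(cnt$gene_id, cnt$seq_name, positions, bases,
                         cnt$support)
  out <- arrange(out, .data$gene_id,
                 map_int(.data$positions, 1L),
                 map_chr(.data$bases, paste0, collapse = ""))
  renumber_patterns(out)
}

#' Filter base patterns containing rare base pairs
#'
#' For every pair of consecutive HSP positions in a gene, the read support
#' of each base combination is tallied over all patterns covering both
#' positions; patterns containing a combination supported by less than
#' `basepair_min_frac` of the total support at that position pair are
#' removed as likely sequencing noise. Consecutiveness is taken in the
#' gene's validated HSP list, regardless of intervening non-HSP bases.
#' Patterns covering a single position are never removed by this rule.
#'
#' @param patterns Pattern tibble.
#' @param hsps Validated HSP tibble (defines the per-gene HSP order).
#' @param genes Gene intervals tibble used to map HSP positions to genes.
#' @param cfg A [core_config()].
#' @return The filtered pattern tibble.
#' @export
filter_rare_basepairs <- function(patterns, hsps, genes,
                                  cfg = core_config()) {
  if (nrow(patterns) == 0L) return(patterns)
  hsp_by_gene <- hsps_by_gene(hsps, genes)
  keep_tbls <- patterns |>
    dplyr::group_split(.data$gene_id) |>
    purrr::map(function(sub) {
      ps <- hsp_by_gene[[sub$gene_id[1L]]]
      if (length(ps) < 2L) return(sub)
      M <- pattern_matrix(sub, ps)
      drop <- rep(FALSE, nrow(sub))
      for (j in seq_len(length(ps) - 1L)) {
        has <- M[, j] > 0L & M[, j + 1L] > 0L
        if (!any(has)) next
        combo <- M[has, j] * 5L + M[has, j + 1L]
        supp <- tapply(sub$support[has], combo, sum)
        total <- sum(supp)
        rare <- as.integer(names(supp))[!frac_ge(supp,
                                                 cfg$basepair_min_frac,
                                                 total)]
        if (length(rare)) {
          idx <- which(has)[combo %in% rare]
          drop[idx] <- TRUE
        }
      }
      sub[!drop, ]
    })
  renumber_patterns(bind_rows(keep_tbls))
}

#' Remove base patterns embedded within another pattern
#'
#' A pattern is removed when all of its (position, base) pairs are contained
#' in some larger pattern of the same gene; its read support is discarded.
#'
#' @param patterns Pattern tibble.
#' @return The pattern tibble without embedded patterns.
#' @export
remove_embedded_patterns <- function(patterns) {
  if (nrow(patterns) == 0L) return(patterns)
  keep_tbls <- patterns |>
    dplyr::group_split(.data$gene_id) |>
    purrr::map(function(sub) {
      if (nrow(sub) < 2L) return(sub)
      ps <- sort(unique(unlist(sub$positions)))
      M <- pattern_matrix(sub, ps)
      pw <- pattern_pairwise(M)
      sizes <- rowSums(M > 0)
      # P embedded in Q: every pair of P agrees with Q, and Q is larger
      emb <- pw$matches == sizes & outer(sizes, sizes, "<")
      diag(emb) <- FALSE
      sub[!apply(emb, 1L, any), ]
    })
  renumber_patterns(bind_rows(keep_tbls))
}

# tie-break representation for a candidate merge: leftmost start of the
# merged pattern, then its concatenated base string, then position string
merge_tiebreak_key <- function(M, i, j, ps) {
  u <- M[i, ]
  take <- u == 0L
  u[take] <- M[j, take]
  cov <- u > 0L
  sprintf("%012d|%s|%s", ps[which(cov)[1L]],
          paste(int_to_base(u[cov]), collapse = ""),
          paste(ps[cov], collapse = ","))
}

#' Iteratively merge overlapping base patterns
#'
#' Two patterns of the same gene can merge when they share at least
#' `min_overlap` HSP positions and agree on the base at every shared
#' position. The pair with the largest overlap is merged first (ties broken
#' deterministically by the merged pattern's leftmost start, then its base
#' string), the merged pattern replaces the two originals with summed
#' support, and the process repeats until no mergeable pair remains. Longer
#' patterns have a better chance of unambiguous subgenome assignment, which
#' is what makes the missing-diploid mode work; merging is therefore on by
#' default exactly when a diploid progenitor is missing.
#'
#' @param patterns Pattern tibble.
#' @param cfg A [core_config()].
#' @return The merged pattern tibble. Total support is conserved.
#' @export
merge_overlapping_patterns <- function(patterns, cfg = core_config()) {
  if (nrow(patterns) == 0L) return(patterns)
  out_tbls <- patterns |>
    dplyr::group_split(.data$gene_id) |>
    purrr::map(function(sub) {
      if (nrow(sub) < 2L) return(sub)
      ps <- sort(unique(unlist(sub$positions)))
      M <- pattern_matrix(sub, ps)
      support <- sub$support
      state <- sub$state
      active <- rep(TRUE, nrow(M))
      pw <- pattern_pairwise(M)
      ov <- ifelse(pw$matches == pw$shared & pw$shared >= cfg$min_overlap,
                   pw$shared, 0L)
      diag(ov) <- 0L
      repeat {
        ov_act <- ov
        ov_act[!active, ] <- 0L
        ov_act[, !active] <- 0L
        best <- max(ov_act)
        if (best == 0L) break
        cand <- which(ov_act == best, arr.ind = TRUE)
        cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
        keys <- vapply(seq_len(nrow(cand)), function(k)
          merge_tiebreak_key(M, cand[k, 1L], cand[k, 2L], ps), character(1))
        pick <- cand[order(keys)[1L], ]
        i <- pick[1L]; j <- pick[2L]
        merged <- M[i, ]
        take <- merged == 0L
        merged[take] <- M[j, take]
        active[c(i, j)] <- FALSE
        M <- rbind(M, merged)
        support <- c(support, support[i] + support[j])
        state <- c(state, "active")
        active <- c(active, TRUE)
        # overlaps of the merged row against the other active rows
        covered_new <- merged > 0L
        new_ov <- integer(nrow(M))
        for (k in which(active)) {
          if (k == nrow(M)) next
          sh <- covered_new & M[k, ] > 0L
          if (sum(sh) >= cfg$min_overlap && all(M[k, sh] == merged[sh])) {
            new_ov[k] <- sum(sh)
          }
        }
        ov <- rbind(cbind(ov, 0L), 0L)
        ov[nrow(M), ] <- new_ov
        ov[, nrow(M)] <- new_ov
      }
      matrix_to_pattern_rows(M[active, , drop = FALSE], support[active],
                             state[active], sub$gene_id[1L],
                             sub$seq_name[1L], ps)
    })
  renumber_patterns(arrange(bind_rows(out_tbls), .data$gene_id,
                            map_int(.data$positions, 1L)))
}

# map positions to the gene interval containing them; NA when in no gene
gene_of_positions <- function(seq_name, pos, genes) {
  out <- rep(NA_character_, length(pos))
  for (sq in unique(seq_name)) {
    gs <- genes[genes$seq_name == sq, ]
    if (nrow(gs) == 0L) next
    gs <- gs[order(gs$start), ]
    sel <- seq_name == sq
    gi <- findInterval(pos[sel], gs$start)
    hit <- gi >= 1L & pos[sel] <= gs$end[pmax(gi, 1L)]
    out[sel][hit] <- gs$gene_id[gi[hit]]
  }
  out
}

# per-gene sorted HSP position vectors, keyed by gene id
hsps_by_gene <- function(hsps, genes) {
  if (nrow(hsps) == 0L) return(list())
  gid <- gene_of_positions(hsps$seq_name, hsps$pos, genes)
  ok <- !is.na(gid)
  lapply(split(hsps$pos[ok], gid[ok]), sort)
}
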