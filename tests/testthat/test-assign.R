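mk_profiles <- function(defs, seq_name = "ref") {
  dplyr::bind_rows(purrr::imap(defs, function(codes, s) {
    tibble::tibble(subgenome = s, seq_name = seq_name,
                   pos = as.integer(names(codes)), code = unname(codes))
  }))
}

asn_genes <- tibble::tibble(gene_id = "g1", seq_name = "ref",
                            start = 1L, end = 1000L)

asn_hsps <- function(pos, observed = list()) {
  tibble::tibble(
    seq_name = "ref", pos = as.integer(pos), ref_base = "A",
    observed_bases = if (length(observed)) observed
                     else rep(list(c("A", "C", "G", "T")), length(pos))
  )
}

test_that("pattern identity is percentage of informative matches", {
  pats <- mk_patterns(list(
    list(pos = c(1, 2, 3, 4), base = c("A", "C", "G", "T"))
  ))
  prof <- mk_profiles(list(
    s1 = c(`1` = "A", `2` = "C", `3` = "G", `4` = "A"),  # 3 of 4 match
    s2 = c(`1` = "T", `2` = "0", `3` = "<", `4` = "*")   # 1 informative
  ))
  out <- assign_patterns_to_subgenomes(pats, prof)
  expect_equal(out$identity[[1]][["s1"]], 75)
  expect_equal(out$identity[[1]][["s2"]], 0)  # only position 1 informative
  expect_equal(out$assigned_to[[1]], "s1")
})

test_that("identity exactly at 50% assigns; multi-assignment is allowed", {
  pats <- mk_patterns(list(
    list(pos = c(1, 2), base = c("A", "C"))
  ))
  prof <- mk_profiles(list(
    s1 = c(`1` = "A", `2` = "G"),   # 50%
    s2 = c(`1` = "A", `2` = "C")    # 100%
  ))
  out <- assign_patterns_to_subgenomes(pats, prof)
  expect_setequal(out$assigned_to[[1]], c("s1", "s2"))
})

test_that("unassignable patterns fall back to the missing subgenome", {
  pats <- mk_patterns(list(
    list(pos = c(1, 2, 3, 4, 5), base = c("A", "C", "G", "T", "A"))
  ))
  prof <- mk_profiles(list(
    s1 = c(`1` = "T", `2` = "G", `3` = "G", `4` = "T", `5` = "C"),  # 40%
    s2 = c(`1` = "A", `2` = "G", `3` = "C", `4` = "G", `5` = "C"),  # 20%
    s3 = c(`1` = "?", `2` = "?", `3` = "?", `4` = "?", `5` = "?")
  ))
  out <- assign_patterns_to_subgenomes(pats, prof, missing = "s3")
  expect_equal(out$assigned_to[[1]], "s3")
  expect_true(is.na(out$identity[[1]][["s3"]]))

  # with no missing subgenome, a pattern with no informative profile
  # positions stays unassigned
  prof2 <- mk_profiles(list(
    s1 = c(`1` = "0", `2` = "0", `3` = "0", `4` = "0", `5` = "0"),
    s2 = c(`1` = "?", `2` = "?", `3` = "?", `4` = "?", `5` = "?")
  ))
  out2 <- assign_patterns_to_subgenomes(pats, prof2)
  expect_equal(length(out2$assigned_to[[1]]), 0L)
})

run_election <- function(defs, prof, hsps, mode = "max", missing = NULL) {
  pats <- mk_patterns(defs)
  pats <- assign_patterns_to_subgenomes(pats, prof, missing = missing,
                                        cfg = core_config(mode = mode))
  assign_bases_to_subgenomes(pats, hsps, asn_genes,
                             subgenomes = unique(prof$subgenome),
                             missing = missing,
                             cfg = core_config(mode = mode))
}

test_that("max mode elects the best pattern's base; ties give no call", {
  hsps <- asn_hsps(c(1, 2))
  # pattern 1 (identity 100 via both positions) carries A at 1; pattern 2
  # (identity 50) carries C at 1
  prof <- mk_profiles(list(
    s1 = c(`1` = "A", `2` = "C"),
    s2 = c(`1` = "G", `2` = "T")
  ))
  calls <- run_election(list(
    list(pos = c(1, 2), base = c("A", "C"), support = 5),
    list(pos = c(1, 2), base = c("C", "C"), support = 5)
  ), prof, hsps)
  expect_equal(calls$assigned_base[calls$pos == 1 &
                                     calls$subgenome == "s1"], "A")

  # exact tie between two bases: no call. Both patterns sit at exactly 50%
  # identity with s1 but disagree at position 1.
  prof_tie <- mk_profiles(list(
    s1 = c(`1` = "A", `2` = "C", `3` = "G"),
    s2 = c(`1` = "T", `2` = "T", `3` = "T")
  ))
  calls_tie <- run_election(list(
    list(pos = c(1, 2), base = c("A", "G"), support = 5),  # s1: 50 (pos 1)
    list(pos = c(1, 3), base = c("C", "G"), support = 5)   # s1: 50 (pos 3)
  ), prof_tie, asn_hsps(c(1, 2, 3)))
  expect_true(is.na(calls_tie$assigned_base[calls_tie$pos == 1 &
                                              calls_tie$subgenome == "s1"]))
})

test_that("additive mode sums identities across patterns", {
  # at position 1: A appears in two patterns with identities 60 and 55
  # (sum 115), C in one with identity 90 -> additive elects A, max elects C
  hsps <- asn_hsps(c(1, 2, 3, 4, 5))
  prof <- mk_profiles(list(
    s1 = c(`1` = "A", `2` = "C", `3` = "G", `4` = "T", `5` = "A"),
    s2 = c(`1` = "C", `2` = "G", `3` = "C", `4` = "G", `5` = "C")
  ))
  defs <- list(
    # identity vs s1: 3/5 = 60
    list(pos = 1:5, base = c("A", "C", "G", "A", "C"), support = 1),
    # identity vs s1: 60 (3 of 5)
    list(pos = 1:5, base = c("A", "C", "A", "C", "A"), support = 1),
    # identity vs s1: 4/5 = 80, carries C at 1
    list(pos = 1:5, base = c("C", "C", "G", "T", "A"), support = 1)
  )
  add <- run_election(defs, prof, hsps, mode = "additive")
  expect_equal(add$assigned_base[add$pos == 1 & add$subgenome == "s1"], "A")
  mx <- run_election(defs, prof, hsps, mode = "max")
  expect_equal(mx$assigned_base[mx$pos == 1 & mx$subgenome == "s1"], "C")
})

test_that("patterns conflicting with elected bases are removed", {
  hsps <- asn_hsps(c(1, 2))
  prof <- mk_profiles(list(
    s1 = c(`1` = "A", `2` = "C"),
    s2 = c(`1` = "G", `2` = "T")
  ))
  calls <- run_election(list(
    list(pos = c(1, 2), base = c("A", "C"), support = 5),   # s1, 100
    list(pos = c(1, 2), base = c("A", "T"), support = 5)    # s1, 50: conflicts at 2
  ), prof, hsps)
  pats <- attr(calls, "patterns")
  expect_equal(sum(pats$state == "removed"), 1L)
  expect_equal(calls$assigned_base[calls$subgenome == "s1"], c("A", "C"))
})

test_that("election equals a brute-force oracle on small instances", {
  set.seed(17)
  positions <- c(10, 20, 30, 40)
  for (rep in 1:25) {
    prof <- mk_profiles(list(
      s1 = setNames(sample(c("A", "C", "G", "T"), 4, TRUE),
                    as.character(positions)),
      s2 = setNames(sample(c("A", "C", "G", "T"), 4, TRUE),
                    as.character(positions))
    ))
    n <- sample(2:6, 1)
    defs <- lapply(seq_len(n), function(i) {
      k <- sample(2:4, 1)
      idx <- sort(sample(1:4, k))
      list(pos = positions[idx],
           base = sample(c("A", "C", "G", "T"), k, TRUE),
           support = sample(1:9, 1))
    })
    mode <- sample(c("max", "additive"), 1)
    calls <- run_election(defs, prof, asn_hsps(positions), mode = mode)

    # oracle: replay the accumulate-and-remove iteration with the cell
    # election done by direct enumeration over candidate bases
    pats <- assign_patterns_to_subgenomes(
      mk_patterns(defs), prof, cfg = core_config(mode = mode))
    table_want <- list()
    alive <- rep(TRUE, nrow(pats))
    repeat {
      changed <- FALSE
      for (s in c("s1", "s2")) {
        for (p in positions) {
          key <- paste(s, p)
          if (!is.null(table_want[[key]])) next
          cand_base <- character(0); cand_score <- numeric(0)
          for (i in which(alive)) {
            if (!s %in% pats$assigned_to[[i]]) next
            j <- match(p, pats$positions[[i]])
            if (is.na(j)) next
            cand_base <- c(cand_base, pats$bases[[i]][j])
            cand_score <- c(cand_score, pats$identity[[i]][[s]])
          }
          b <- oracle_elect(cand_base, cand_score, mode)
          if (!is.na(b)) { table_want[[key]] <- b; changed <- TRUE }
        }
      }
      removed <- FALSE
      for (i in which(alive)) {
        for (s in pats$assigned_to[[i]]) {
          for (k in seq_along(pats$positions[[i]])) {
            key <- paste(s, pats$positions[[i]][k])
            if (!is.null(table_want[[key]]) &&
                table_want[[key]] != pats$bases[[i]][k]) {
              alive[i] <- FALSE; removed <- TRUE
            }
          }
        }
      }
      if (!changed && !removed) break
    }
    for (s in c("s1", "s2")) {
      for (p in positions) {
        want <- table_want[[paste(s, p)]] %||% NA_character_
        got <- calls$assigned_base[calls$pos == p & calls$subgenome == s]
        expect_identical(got, want,
                         label = sprintf("rep %d pos %d %s (%s)",
                                         rep, p, s, mode))
      }
    }
  }
})

test_that("raising identity_min never adds pattern assignments", {
  set.seed(41)
  positions <- c(10, 20, 30, 40, 50)
  pats <- random_patterns(12, positions = positions)
  prof <- mk_profiles(list(
    s1 = setNames(sample(c("A", "C", "G", "T"), 5, TRUE),
                  as.character(positions)),
    s2 = setNames(sample(c("A", "C", "G", "T"), 5, TRUE),
                  as.character(positions))
  ))
  prev <- NULL
  for (im in c(0.3, 0.5, 0.7, 0.9)) {
    out <- assign_patterns_to_subgenomes(pats, prof,
                                         cfg = core_config(identity_min = im))
    n_pairs <- sum(lengths(out$assigned_to))
    if (!is.null(prev)) expect_lte(n_pairs, prev)
    prev <- n_pairs
  }
})

test_that("elimination completes a position when one base and one slot remain", {
  hsps <- asn_hsps(1, observed = list(c("A", "G")))
  prof <- mk_profiles(list(s1 = c(`1` = "A"), s2 = c(`1` = "0")))
  pats <- mk_patterns(list(list(pos = 1, base = "A", support = 3)))
  pats <- assign_patterns_to_subgenomes(pats, prof)
  calls <- assign_bases_to_subgenomes(pats, hsps, asn_genes,
                                      subgenomes = c("s1", "s2"))
  expect_true(is.na(calls$assigned_base[calls$subgenome == "s2"]))
  fin <- finalize_assignments(calls, attr(calls, "patterns"))
  expect_equal(fin$assigned_base[fin$subgenome == "s2"], "G")
  expect_true(all(fin$fully_characterized))

  # two unassigned bases: no elimination
  hsps3 <- asn_hsps(1, observed = list(c("A", "C", "G")))
  calls3 <- assign_bases_to_subgenomes(pats, hsps3, asn_genes,
                                       subgenomes = c("s1", "s2"))
  fin3 <- finalize_assignments(calls3, attr(calls3, "patterns"))
  expect_true(is.na(fin3$assigned_base[fin3$subgenome == "s2"]))

  # finalization off returns the calls unchanged
  off <- finalize_assignments(calls, attr(calls, "patterns"),
                              cfg = core_config(finalize = FALSE))
  expect_identical(off$assigned_base, calls$assigned_base)
})
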