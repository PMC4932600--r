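mk_cov <- function(pos, A = 0L, C = 0L, G = 0L, T = 0L, seq_name = "ref") {
  tibble::tibble(seq_name = seq_name, pos = as.integer(pos),
                 A = as.integer(A), C = as.integer(C),
                 G = as.integer(G), T = as.integer(T))
}

mk_hsp <- function(pos, ref, observed, seq_name = "ref") {
  tibble::tibble(seq_name = seq_name, pos = as.integer(pos), ref_base = ref,
                 observed_bases = list(observed))
}

test_that("HSP validation applies the 5% rule at the boundary", {
  cfg <- preprocess_config()
  # 4 of 100 fails 5%, leaving one base: position dropped
  out <- validate_hsps(mk_hsp(10, "A", c("A", "C")),
                       mk_cov(10, A = 96, C = 4), cfg)
  expect_equal(nrow(out), 0L)
  # 5 of 100 meets "at least 5%": both valid
  out <- validate_hsps(mk_hsp(10, "A", c("A", "C")),
                       mk_cov(10, A = 95, C = 5), cfg)
  expect_equal(out$observed_bases[[1]], c("A", "C"))
  # symmetric 50/50
  out <- validate_hsps(mk_hsp(10, "A", c("A", "C")),
                       mk_cov(10, A = 50, C = 50), cfg)
  expect_equal(lengths(out$observed_bases), 2L)
  # position absent from coverage: dropped and counted
  out <- validate_hsps(mk_hsp(11, "A", c("A", "C")),
                       mk_cov(10, A = 50, C = 50), cfg)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_dropped"), 1L)
  # no coverage table: validation skipped
  hsps <- mk_hsp(10, "A", c("A", "C"))
  expect_identical(validate_hsps(hsps, NULL, cfg), hsps)
})

test_that("SBS validation applies the 30% rule at the boundary", {
  cfg <- preprocess_config()
  sbs <- tibble::tibble(seq_name = "ref", pos = 10L, ref_base = "G",
                        diploid_base = "T")
  expect_equal(nrow(validate_sbss(sbs, mk_cov(10, T = 3, G = 7), cfg)), 1L)
  out <- validate_sbss(sbs, mk_cov(10, T = 2, G = 8), cfg)
  expect_equal(nrow(out), 0L)
  out <- validate_sbss(sbs, mk_cov(11, T = 9), cfg)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_dropped"), 1L)
})

test_that("validation thresholds are monotone", {
  set.seed(5)
  cov <- tibble::tibble(
    seq_name = "ref", pos = 1:50,
    A = sample(0:30, 50, TRUE), C = sample(0:30, 50, TRUE),
    G = sample(0:30, 50, TRUE), T = sample(0:30, 50, TRUE)
  )
  hsps <- tibble::tibble(seq_name = "ref", pos = 1:50, ref_base = "A",
                         observed_bases = rep(list(c("A", "C", "G", "T")),
                                              50))
  sbss <- tibble::tibble(seq_name = "ref", pos = 1:50, ref_base = "A",
                         diploid_base = sample(c("C", "G", "T"), 50, TRUE))
  fracs <- c(0.05, 0.1, 0.2, 0.35, 0.5)
  prev_h <- NULL; prev_s <- NULL
  for (f in fracs) {
    h <- validate_hsps(hsps, cov, preprocess_config(hsp_min_frac = f))
    s <- validate_sbss(sbss, cov, preprocess_config(sbs_min_frac = f))
    if (!is.null(prev_h)) {
      expect_true(all(h$pos %in% prev_h$pos))
      expect_true(all(s$pos %in% prev_s$pos))
      # surviving base sets only shrink
      common <- intersect(h$pos, prev_h$pos)
      for (p in common) {
        expect_true(all(h$observed_bases[[match(p, h$pos)]] %in%
                          prev_h$observed_bases[[match(p, prev_h$pos)]]))
      }
    }
    prev_h <- h; prev_s <- s
  }
})

test_that("HSP discovery adds qualifying SBS positions once", {
  cfg <- preprocess_config()
  existing <- mk_hsp(10, "A", c("A", "C"))
  sbs_list <- list(d1 = tibble::tibble(seq_name = "ref",
                                       pos = c(10L, 20L, 30L),
                                       ref_base = c("A", "C", "T"),
                                       diploid_base = c("C", "T", "A")))
  poly_cov <- dplyr::bind_rows(
    mk_cov(10, A = 50, C = 50),
    mk_cov(20, C = 40, T = 60),   # two valid bases -> new HSP
    mk_cov(30, T = 98, C = 2)     # one valid base -> no HSP
  )
  out <- discover_additional_hsps(sbs_list, NULL, poly_cov, existing, cfg)
  expect_equal(out$pos, c(10L, 20L))
  expect_equal(out$observed_bases[[2]], c("C", "T"))
  expect_equal(attr(out, "n_discovered"), 1L)
  # fixed point: a second run discovers nothing new
  again <- discover_additional_hsps(sbs_list, NULL, poly_cov, out, cfg)
  expect_equal(again$pos, out$pos)
  expect_equal(attr(again, "n_discovered"), 0L)
  # candidate with no polyploid coverage is skipped
  sbs_list$d1 <- dplyr::bind_rows(
    sbs_list$d1, tibble::tibble(seq_name = "ref", pos = 40L,
                                ref_base = "G", diploid_base = "A"))
  out2 <- discover_additional_hsps(sbs_list, NULL, poly_cov, existing, cfg)
  expect_false(40L %in% out2$pos)
})

test_that("extra positions are considered for HSP discovery", {
  p <- tempfile()
  writeLines(c("#seq\tpos\tref", "ref\t20\tC"), p)
  extra <- read_extra_positions(p)
  expect_equal(extra$pos, 20L)
  out <- discover_additional_hsps(list(), extra, mk_cov(20, C = 40, T = 60),
                                  mk_hsp(10, "A", c("A", "C"))[0, ],
                                  preprocess_config())
  expect_equal(out$pos, 20L)
})

test_that("diploid profiles encode SBS, coverage classes and missing data", {
  cfg <- preprocess_config()
  hsps <- dplyr::bind_rows(
    mk_hsp(5, "G", c("G", "T")), mk_hsp(6, "A", c("A", "C")),
    mk_hsp(7, "A", c("A", "C")), mk_hsp(8, "A", c("A", "C")),
    mk_hsp(9, "A", c("A", "C"))
  )
  sbs_list <- list(
    dA = tibble::tibble(seq_name = "ref", pos = 5L, ref_base = "G",
                        diploid_base = "T")
  )
  dip_cov <- list(dA = dplyr::bind_rows(
    mk_cov(6, A = 2),             # 0 < total < 3 -> low coverage
    mk_cov(7, A = 5, C = 5),      # two bases at >= 20% -> ambiguous
    mk_cov(8, A = 9, C = 1)       # clear majority
  ))                              # pos 9 absent -> no coverage
  prof <- build_diploid_profiles(sbs_list, dip_cov, hsps,
                                 missing = "dB", cfg = cfg)
  pa <- prof[prof$subgenome == "dA", ]
  expect_equal(pa$code[pa$pos == 5], "T")   # SBS precedence
  expect_equal(pa$code[pa$pos == 6], "<")
  expect_equal(pa$code[pa$pos == 7], "*")
  expect_equal(pa$code[pa$pos == 8], "A")
  expect_equal(pa$code[pa$pos == 9], "0")
  pb <- prof[prof$subgenome == "dB", ]
  expect_true(all(pb$code == "?"))

  # no coverage table at all: reference-base fallback
  prof2 <- build_diploid_profiles(sbs_list, NULL, hsps, cfg = cfg)
  p2 <- prof2[prof2$subgenome == "dA", ]
  expect_equal(p2$code[p2$pos == 6], "A")

  expect_error(
    build_diploid_profiles(sbs_list, NULL, hsps,
                           missing = c("dB", "dC"), cfg = cfg),
    "at most one"
  )
})
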