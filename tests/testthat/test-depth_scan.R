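cohort2 <- make_cohort(2, 2)

depth_of <- function(vals_by_contig, cohort) {
  lapply(vals_by_contig, function(v) {
    m <- matrix(rep(as.integer(v), nrow(cohort)), ncol = nrow(cohort),
                dimnames = list(NULL, cohort$sample_id))
    m
  })
}

test_that("depth binning tiles contigs and averages partial final windows", {
  b <- bin_depths(depth_of(list(c1 = rep(10, 1000)), cohort2), cohort2)
  expect_equal(nrow(b$windows), 1)
  expect_equal(b$windows$end, 1000)
  expect_true(all(b$means == 10))

  b <- bin_depths(depth_of(list(c1 = rep(2, 1500)), cohort2), cohort2)
  expect_equal(b$windows$start, c(0, 1000))
  expect_equal(b$windows$end, c(1000, 1500))
  expect_true(all(b$means == 2))

  # tiling covers every base exactly once
  widths <- b$windows$end - b$windows$start
  expect_equal(sum(widths), 1500)
  expect_true(all(b$windows$start[-1] == b$windows$end[-nrow(b$windows)]))

  expect_error(
    bin_depths(list(c1 = matrix(0L, 10, 1, dimnames = list(NULL, "M01"))),
               cohort2),
    "missing sample")
})

test_that("window means equal a per-window arithmetic-mean oracle", {
  set.seed(31)
  len <- 3307
  cohort <- make_cohort(3, 2)
  depth <- list(c1 = matrix(rpois(len * 5, 8), ncol = 5,
                            dimnames = list(NULL, cohort$sample_id)))
  b <- bin_depths(depth, cohort, bin_width = 250)
  for (w in seq_len(nrow(b$windows))) {
    rows <- (b$windows$start[w] + 1):b$windows$end[w]
    for (s in cohort$sample_id) {
      expect_equal(unname(b$means[w, s]), mean(depth$c1[rows, s]))
    }
  }
})

test_that("Welch window tests agree with t.test and honour degeneracy rules", {
  cohort <- make_cohort(7, 6)

  # identical multisets of means -> no signal
  binned <- list(windows = data.frame(contig = "c1", start = 0, end = 1000),
                 means = matrix(rep(5, 13), nrow = 1,
                                dimnames = list(NULL, cohort$sample_id)))
  ws <- welch_window_tests(binned, cohort)
  expect_equal(ws$t, 0)
  expect_equal(ws$p, 1)
  expect_equal(ws$neg_log10_p, 0)

  # the worked 7-vs-6 configuration against stats::t.test
  m <- c(12, 14, 13, 12, 14, 13, 12); f <- c(13, 12, 14, 13, 12, 14)
  binned$means <- matrix(c(m, f), nrow = 1,
                         dimnames = list(NULL, cohort$sample_id))
  ws <- welch_window_tests(binned, cohort)
  ref <- t.test(m, f)
  expect_equal(ws$p, ref$p.value, tolerance = 1e-12)
  expect_equal(ws$t, unname(ref$statistic), tolerance = 1e-12)

  # random windows against the independent implementation
  set.seed(7)
  means <- matrix(rnorm(200 * 13, 13, 2), ncol = 13,
                  dimnames = list(NULL, cohort$sample_id))
  binned <- list(windows = data.frame(contig = "c1", start = 1000 * (0:199),
                                      end = 1000 * (1:200)),
                 means = means)
  ws <- welch_window_tests(binned, cohort)
  for (i in seq_len(50)) {
    ref <- t.test(means[i, 1:7], means[i, 8:13])
    expect_equal(ws$p[i], ref$p.value, tolerance = 1e-9)
  }

  # both variances zero, unequal means: floored p, capped -log10P
  binned <- list(windows = data.frame(contig = "c1", start = 0, end = 1000),
                 means = matrix(c(rep(13, 7), rep(0, 6)), nrow = 1,
                                dimnames = list(NULL, cohort$sample_id)))
  ws <- welch_window_tests(binned, cohort)
  expect_equal(ws$p, 1e-300)
  expect_equal(ws$neg_log10_p, 300)

  # one-sided zero variance proceeds through the Welch formula
  binned$means <- matrix(c(12:14, 12:14, 12, rep(0, 6)), nrow = 1,
                         dimnames = list(NULL, cohort$sample_id))
  ws <- welch_window_tests(binned, cohort)
  expect_true(is.finite(ws$t) && ws$p > 0 && ws$p < 1e-6)

  expect_error(welch_window_tests(binned, make_cohort(1, 2)), "at least 2")
})

test_that("sex-label swap negates t and preserves p", {
  set.seed(9)
  cohort <- make_cohort(7, 6)
  swapped <- cohort
  swapped$sex <- ifelse(cohort$sex == "MALE", "FEMALE", "MALE")
  means <- matrix(rnorm(100 * 13, 10, 3), ncol = 13,
                  dimnames = list(NULL, cohort$sample_id))
  binned <- list(windows = data.frame(contig = "c1", start = 1000 * (0:99),
                                      end = 1000 * (1:100)),
                 means = means)
  a <- welch_window_tests(binned, cohort)
  b <- welch_window_tests(binned, swapped)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
})

test_that("window retention is strictly greater-than and sorted", {
  ws <- data.frame(contig = c("b", "a", "a"), start = c(0, 2000, 0),
                   end = c(1000, 3000, 1000),
                   male_mean = 1, female_mean = 1, t = 1,
                   p = c(10^-2, 10^-2.0001, 10^-5),
                   neg_log10_p = c(2, 2.0001, 5))
  kept <- filter_depth_windows(ws, threshold = 2)
  expect_equal(nrow(kept), 2)
  expect_false(any(kept$neg_log10_p == 2))    # exactly 2.0 dropped
  expect_equal(kept$contig, c("a", "a"))
  expect_equal(kept$start, c(0, 2000))        # sorted by contig, start

  expect_equal(nrow(filter_depth_windows(ws[0, ], 2)), 0)
  # threshold 0 keeps all windows with p < 1
  expect_equal(nrow(filter_depth_windows(ws, 0)), 3)
})

test_that("zero-depth tracts are maximal, sex-specific and strict", {
  cohort <- make_cohort(7, 6)
  len <- 1000
  depth <- list(c1 = matrix(13L, nrow = len, ncol = 13,
                            dimnames = list(NULL, cohort$sample_id)))
  fem <- cohort$sample_id[cohort$sex == "FEMALE"]
  depth$c1[101:600, fem] <- 0L
  tr <- zero_depth_tracts(depth, cohort, "FEMALE", min_tract_len = 500)
  expect_equal(tr[, c("start", "end")], data.frame(start = 100, end = 600))
  expect_equal(tr$sex, "FEMALE")
  expect_equal(nrow(zero_depth_tracts(depth, cohort, "MALE",
                                      min_tract_len = 10)), 0)

  # one female with depth 1 at offset 300 splits the tract
  depth$c1[301, fem[1]] <- 1L
  tr <- zero_depth_tracts(depth, cohort, "FEMALE", min_tract_len = 100)
  expect_equal(tr$start, c(100, 301))
  expect_equal(tr$end, c(300, 600))
  # but is tolerated when max_allowed_depth = 1
  tr <- zero_depth_tracts(depth, cohort, "FEMALE", max_allowed_depth = 1,
                          min_tract_len = 100)
  expect_equal(tr[, c("start", "end")], data.frame(start = 100, end = 600))
})

test_that("tract calls equal an exhaustive per-base AND-scan oracle", {
  set.seed(17)
  cohort <- make_cohort(3, 3)
  len <- 2000
  for (rep in 1:3) {
    m <- matrix(rpois(len * 6, 2), ncol = 6,
                dimnames = list(NULL, cohort$sample_id))
    tr <- zero_depth_tracts(list(c1 = m), cohort, "FEMALE",
                            max_allowed_depth = 0, min_tract_len = 3)
    fem <- cohort$sample_id[cohort$sex == "FEMALE"]
    ok <- apply(m[, fem] <= 0, 1, all)
    covered <- logical(len)
    for (i in seq_len(nrow(tr))) covered[(tr$start[i] + 1):tr$end[i]] <- TRUE
    # every covered base passes; every uncovered run passing is shorter than 3
    expect_true(all(ok[covered]))
    r <- rle(ok & !covered)
    expect_true(all(r$lengths[r$values] < 3))
  }
})

test_that("depth scan p-values are calibrated on a null cohort", {
  # one 5 Mb contig, no sex effect: the retained fraction at -log10P > 2
  # sits at the small-sample t excess over the nominal 1%
  cfg <- simulation_config(
    data.frame(contig = "null_ctg", length = 5e6), features = list(),
    seed = 424242)
  sim <- simulate_cohort(cfg)
  b <- bin_depths(sim$depth, sim$cohort)
  ws <- welch_window_tests(b, sim$cohort)
  frac <- mean(ws$neg_log10_p > 2)
  expect_gt(frac, 0.001)
  expect_lt(frac, 0.05)
})

test_that("stronger planted depth contrast never weakens window retention", {
  counts <- vapply(c(1, 0.5, 0), function(fac) {
    contigs <- data.frame(contig = "c1", length = 30000)
    cfg <- simulation_config(
      contigs,
      features = list(planted_feature("XY_SDR", "c1", 0, 6000,
                                      het_depth_factor = 1,
                                      hom_depth_factor = fac)),
      seed = 99)
    sim <- simulate_cohort(cfg)
    ws <- welch_window_tests(bin_depths(sim$depth, sim$cohort), sim$cohort)
    kept <- filter_depth_windows(ws)
    sum(kept$start < 6000)
  }, 0)
  expect_true(all(diff(counts) >= 0))
})
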