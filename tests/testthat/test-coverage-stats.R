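test_that("coverage statistic sums qualifying tract lengths over L", {
  r <- compute_coverage(matrix(c(0, 600), ncol = 2), L = 1000)
  expect_equal(r$coverage, 0.6)
  expect_equal(r$n_tracts, 1L)

  # tract below the 500 bp minimum contributes nothing
  r <- compute_coverage(matrix(c(0, 400), ncol = 2), L = 1000)
  expect_equal(r$coverage, 0)
  expect_equal(r$n_tracts, 0L)

  r <- compute_coverage(rbind(c(0, 500), c(600, 1100)), L = 10000)
  expect_equal(r$coverage, 0.1)
  expect_equal(r$n_tracts, 2L)

  # min_tract_bp = 0 recovers the plain length fraction; monotone in tracts
  tr <- rbind(c(0, 400), c(1000, 1600))
  expect_equal(compute_coverage(tr, 10000, min_tract_bp = 0)$coverage, 0.1)
  expect_gte(compute_coverage(tr, 10000, 0)$coverage,
             compute_coverage(tr[2, , drop = FALSE], 10000, 0)$coverage)

  # unmerged input is the caller's bug
  expect_error(compute_coverage(rbind(c(0, 500), c(400, 900)), 1000),
               "domain error")
  expect_error(compute_coverage(rbind(c(0, 500), c(500, 900)), 1000),
               "domain error")
  expect_error(compute_coverage(matrix(c(500, 1200), ncol = 2), 1000),
               "domain error")
})

test_that("expected haplotype ratio is 2/(1+p), decreasing on [0,1]", {
  expect_equal(expected_haplotype_ratio(1), 1)
  expect_equal(expected_haplotype_ratio(0), 2)
  expect_equal(expected_haplotype_ratio(0.5), 4 / 3)
  p <- seq(0, 1, by = 0.01)
  expect_true(all(diff(expected_haplotype_ratio(p)) < 0))
  expect_error(expected_haplotype_ratio(1.1), "domain error")
  expect_error(expected_haplotype_ratio(-0.1), "domain error")
})

test_that("bootstrap ratio handles degenerate pools and matches brute force", {
  # constant pools: exact ratio, zero-width CI
  est <- bootstrap_ratio(rep(0.02, 5), rep(0.01, 5), n_per_draw = 100,
                         n_boot = 50, seed = 1)
  expect_equal(est$mean_ratio, 2)
  expect_equal(est$ci_low, 2)
  expect_equal(est$ci_high, 2)
  est <- bootstrap_ratio(rep(0.03, 4), rep(0.03, 4), n_per_draw = 10,
                         n_boot = 20, seed = 1)
  expect_equal(est$mean_ratio, 1)

  # small pools: agree with an independent bulk resampler within 2%
  aut <- c(0.010, 0.020, 0.025, 0.030, 0.015)
  x <- c(0.004, 0.009, 0.011, 0.006, 0.010)
  est <- bootstrap_ratio(aut, x, n_per_draw = 5, n_boot = 2000, seed = 7)
  set.seed(99)
  nb <- 1e5
  oracle <- mean(vapply(seq_len(nb), function(i) {
    mean(sample(aut, 5, replace = TRUE)) / mean(sample(x, 5, replace = TRUE))
  }, numeric(1)))
  expect_equal(est$mean_ratio, oracle, tolerance = 0.02)
  expect_lte(est$ci_low, est$mean_ratio)
  expect_gte(est$ci_high, est$mean_ratio)

  # zero-mean X resamples are rejected and flagged when frequent
  expect_warning(
    bootstrap_ratio(rep(0.02, 3), c(0, 0, 0.01), n_per_draw = 2,
                    n_boot = 200, seed = 3),
    "unreliable"
  )
})

test_that("sex-bias correlation behaves on exact, null and error cases", {
  p <- rep(seq(0, 1, by = 0.25), each = 40)
  # noiseless linear relation
  r <- sexbias_coverage_correlation(p, 0.01 + 0.02 * p)
  expect_equal(r$rho, 1)
  # independence: near-zero correlation at n = 1e4
  set.seed(42)
  p2 <- rep(seq(0, 1, by = 0.25), each = 2000)
  r0 <- sexbias_coverage_correlation(p2, sample(0.01 + 0.02 * p2))
  expect_lt(abs(r0$rho), 0.05)
  expect_error(sexbias_coverage_correlation(rep(0.5, 10), runif(10)),
               "undefined-correlation")
})

test_that("timecourse summary reproduces means and flags variance decay", {
  rec <- data.frame(generation = rep(c(1, 3, 5), each = 4),
                    coverage = c(rep(0.05, 4), rep(0.04, 4), rep(0.03, 4)))
  tc <- timecourse_summary(rec, n_boot = 50, seed = 1)
  expect_equal(tc$mean_coverage, c(0.05, 0.04, 0.03))
  expect_equal(tc$variance_coverage, c(0, 0, 0))
  expect_equal(tc$ci_low, tc$mean_coverage)

  # single-generation constant coverage: CI collapses to the mean
  one <- timecourse_summary(data.frame(generation = 1, coverage = rep(0.2, 5)),
                            n_boot = 20, seed = 1)
  expect_equal(one$ci_low, 0.2)
  expect_equal(one$ci_high, 0.2)
})

test_that("half-decay generation follows the threshold rule", {
  tc <- data.frame(generation = c(1, 3, 5, 7, 100),
                   mean_coverage = c(0.050, 0.045, 0.040, 0.035, 0.030))
  hd <- half_decay_generation(tc)
  expect_equal(hd$threshold, 0.040)
  expect_equal(hd$generation, 5)
  expect_false(hd$no_decay)

  # constant series: generation 1 with the no-decay flag
  flat <- data.frame(generation = c(1, 10, 100), mean_coverage = rep(0.05, 3))
  hd <- half_decay_generation(flat)
  expect_equal(hd$generation, 1)
  expect_true(hd$no_decay)

  expect_error(half_decay_generation(
    data.frame(generation = c(2, 10), mean_coverage = c(1, 0))),
    "contract error")
})
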