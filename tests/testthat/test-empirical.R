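write_calls <- function(dir, id, hap, df) {
  path <- file.path(dir, sprintf("%s_hap%d.tsv", id, hap))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

call_df <- function(chrom, start, end, posterior = 0.95, snps = 3L) {
  data.frame(chrom = chrom, start = start, end = end, posterior = posterior,
             n_support_snps = snps)
}

lens <- data.frame(chrom = c("chr1", "chrX"), length = c(1e8, 1.55e8))

test_that("ingestion normalizes dialects and enforces paired files", {
  d <- withr::local_tempdir()
  write_calls(d, "A", 1, call_df("chr1", 101, 200))
  write_calls(d, "A", 2, call_df("chr1", 1, 2)[0, ])

  # pos1: 1-based closed [101, 200] becomes 0-based half-open [100, 200)
  calls <- ingest_tracts(d, dialect = "pos1")
  expect_equal(calls$start, 100)
  expect_equal(calls$end, 200)

  calls0 <- ingest_tracts(d, dialect = "bed0")
  expect_equal(calls0$start, 101)

  # missing second haplotype file is an error
  write_calls(d, "B", 1, call_df("chr1", 0, 1000))
  expect_error(ingest_tracts(d), "missing haplotype file")
  file.remove(file.path(d, "B_hap1.tsv"))

  # empty file yields zero calls, zero coverage downstream
  expect_identical(sum(calls$individual_id == "A" & calls$haplotype_index == 2),
                   0L)
})

test_that("filters apply the posterior, SNP-support and PAR rules exactly", {
  calls <- rbind(
    call_df("chr1", 0, 1000, posterior = 0.79),       # removed: < 0.8
    call_df("chr1", 0, 1000, posterior = 0.80),       # kept: boundary
    call_df("chr1", 2000, 3000, posterior = 0.95, snps = 0L),  # removed
    call_df("chrX", 2999999, 3500000),                # removed: PAR overlap 1bp
    call_df("chrX", 3000000, 3500000)                 # kept: abuts PAR
  )
  calls$individual_id <- "A"
  calls$haplotype_index <- 1L
  f <- filter_tracts(calls, par = c(0, 3e6))
  expect_identical(nrow(f), 2L)
  expect_equal(f$posterior[1], 0.80)
  expect_equal(f$start[2], 3000000)

  # SNP-support filter can be switched off
  f2 <- filter_tracts(calls, require_snp_support = FALSE, par = c(0, 3e6))
  expect_identical(nrow(f2), 3L)
})

test_that("per-bp rates use 2L denominators, PAR exclusion and merging", {
  calls <- rbind(
    call_df("chr1", 0, 1e6),
    call_df("chr1", 5e6, 6e6),    # 2 Mb autosomal total on hap 1
    call_df("chrX", 1e7, 1.076e7) # 0.76 Mb X on hap 1
  )
  calls$individual_id <- "A"
  calls$haplotype_index <- 1L
  calls2 <- calls
  calls2$haplotype_index <- 2L  # duplicate on hap 2 -> doubles the bp
  both <- rbind(calls, calls2)

  r <- per_bp_rate(both, lens, par = c(0, 3e6))
  expect_equal(r$aut_rate, 4e6 / (2 * 1e8))
  expect_equal(r$chrx_rate, 1.52e6 / (2 * 1.52e8))
  expect_equal(r$ratio, r$aut_rate / r$chrx_rate)

  # overlapping duplicate calls on one haplotype merge before rates
  dup <- rbind(calls, within(calls, {start <- start + 1000; end <- end + 1000}))
  r2 <- per_bp_rate(dup, lens, par = c(0, 3e6))
  expect_equal(r2$aut_rate, (2e6 + 2000) / (2 * 1e8))

  # splitting a tract into adjacent pieces leaves the rate unchanged
  split <- rbind(call_df("chr1", 0, 5e5), call_df("chr1", 5e5, 1e6))
  split$individual_id <- "S"
  split$haplotype_index <- 1L
  whole <- call_df("chr1", 0, 1e6)
  whole$individual_id <- "W"
  whole$haplotype_index <- 1L
  rr <- per_bp_rate(rbind(split, whole), lens, par = c(0, 3e6))
  expect_equal(rr$aut_rate[rr$individual_id == "S"],
               rr$aut_rate[rr$individual_id == "W"])

  # no tracts at all: zero rates, undefined ratio
  none <- call_df("chr1", 0, 1000)[0, ]
  none$individual_id <- character(0)
  none$haplotype_index <- integer(0)
  r0 <- per_bp_rate(rbind(both[0, ],
                          cbind(call_df("chrX", 0, 1000, 0.9),
                                individual_id = "Z", haplotype_index = 1L)),
                    lens, par = c(3e6, 6e6))
  expect_true(is.finite(r0$chrx_rate))
})

test_that("outlier exclusion uses strict inequalities", {
  ind <- data.frame(individual_id = c("a", "b", "c", "d", "e"),
                    aut_rate = c(0.02, 0.11, 0.1, 0.02, 0.02),
                    chrx_rate = c(0.001, 0.02, 0.02, 0.0004, 0.0004 + 1e-12),
                    ratio = c(20, 5.5, 5, 50, 51))
  ind$ratio <- ind$aut_rate / ind$chrx_rate
  ind$ratio[4] <- 50
  ind$ratio[5] <- 51
  kept <- exclude_outliers(ind)
  expect_setequal(kept$individual_id, c("a", "c", "d"))
})

test_that("group summaries recover planted orderings and can rank differently", {
  set.seed(10)
  mk <- function(group, n, aut, x) {
    data.frame(individual_id = paste0(group, seq_len(n)), group = group,
               aut_rate = aut * exp(rnorm(n, 0, 0.05)),
               chrx_rate = x * exp(rnorm(n, 0, 0.05))) |>
      transform(ratio = aut_rate / chrx_rate)
  }
  ind <- rbind(mk("EASlike", 30, 0.026, 0.007), mk("EURlike", 30, 0.021, 0.004))
  gs <- group_summary(ind, n_boot = 500, seed = 2)
  expect_equal(gs$rankings$aut_rate, c("EURlike", "EASlike"))
  expect_equal(gs$rankings$chrx_rate, c("EURlike", "EASlike"))
  # EUR-like has lower coverage but HIGHER ratio: rankings differ by metric
  expect_equal(gs$rankings$ratio, c("EASlike", "EURlike"))
  # recovered group mean close to the planted mean
  s <- gs$summary
  x <- ind$aut_rate[ind$group == "EASlike"]
  expect_lt(abs(s$aut_rate[s$group == "EASlike"] - 0.026),
            3 * stats::sd(x) / sqrt(length(x)) + 0.026 * 0.05^2)

  # constant rates: zero-width CI
  const <- data.frame(individual_id = 1:4, group = "G",
                      aut_rate = 0.02, chrx_rate = 0.005, ratio = 4)
  cs <- group_summary(const, n_boot = 100, seed = 1)$summary
  expect_equal(cs$aut_ci_low, cs$aut_ci_high)
  # singleton group: mean only
  single <- data.frame(individual_id = "x", group = "S",
                       aut_rate = 0.01, chrx_rate = 0.002, ratio = 5)
  ss <- group_summary(single, n_boot = 10, seed = 1)$summary
  expect_true(is.na(ss$aut_ci_low))
  expect_equal(ss$aut_rate, 0.01)
})

test_that("Welch tests use the alpha/n_pairs Bonferroni threshold", {
  set.seed(3)
  ind <- do.call(rbind, lapply(c("A", "B", "C", "D"), function(g) {
    data.frame(individual_id = paste0(g, 1:10), group = g,
               aut_rate = rnorm(10, 0.02, 0.001), chrx_rate = 0.005,
               ratio = 4)
  }))
  pw <- pairwise_welch(ind, "aut_rate")
  expect_equal(pw$threshold, 0.05 / 6)
  expect_identical(nrow(pw$tests), 6L)

  # hand-computable Welch case: {0, 2} vs {10, 12}
  ind2 <- data.frame(individual_id = 1:4, group = rep(c("g1", "g2"), each = 2),
                     aut_rate = c(0, 2, 10, 12), chrx_rate = 1, ratio = 1)
  pw2 <- pairwise_welch(ind2, "aut_rate")
  # t = (mean1 - mean2) / sqrt(s1^2/n1 + s2^2/n2) = -10 / sqrt(1 + 1)
  expect_equal(pw2$tests$t, -10 / sqrt(2))

  # identical constant groups: p = 1 by convention, not significant
  ind3 <- data.frame(individual_id = 1:6, group = rep(c("u", "v"), each = 3),
                     aut_rate = 0.02, chrx_rate = 0.004, ratio = 5)
  pw3 <- pairwise_welch(ind3, "aut_rate")
  expect_equal(pw3$tests$p, 1)
  expect_false(pw3$tests$significant)
})

test_that("published-estimate summary takes the median ratio", {
  est <- data.frame(aut_rate = c(0.02, 0.03, 0.01, 0.025),
                    chrx_rate = c(0.02 / 8, 0.03 / 6.9, 0.01 / 5, 0.025 / 2))
  ps <- published_ratio_summary(est)
  expect_equal(ps$median_ratio, stats::median(c(8, 6.9, 5, 2)))
  expect_equal(ps$n, 4L)
  ps2 <- published_ratio_summary(est, subset = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ps2$median_ratio, stats::median(c(8, 6.9)))
})
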