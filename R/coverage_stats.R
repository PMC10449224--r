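#' Archaic coverage of a haplotype
#'
#' Coverage is the fraction of a haplotype's base pairs contained in archaic
#' ancestry tracts of at least `min_tract_bp` (default 500 bp):
#' `c_h = sum(t_end - t_start) / L` over qualifying tracts. Tracts shorter
#' than the minimum contribute nothing. `min_tract_bp = 0` recovers the plain
#' length fraction.
#'
#' @param tracts two-column matrix of tract intervals `[start, end)` in bp,
#'   sorted, disjoint and merged (overlapping or endpoint-sharing tracts are a
#'   domain error; merge first).
#' @param L haplotype length in bp.
#' @param min_tract_bp minimum qualifying tract length in bp.
#' @param haplotype_id,generation optional annotations carried into the record.
#' @return One-row data frame (class `coverage_record`) with columns
#'   `haplotype_id`, `generation`, `coverage`, `n_tracts`, `total_tract_bp`.
#' @export
compute_coverage <- function(tracts, L, min_tract_bp = 500,
                             haplotype_id = NA_integer_,
                             generation = NA_integer_) {
  stopifnot(L > 0, min_tract_bp >= 0)
  tracts <- as.matrix(tracts)
  if (nrow(tracts) > 0) {
    if (!is_merged(tracts)) {
      stop("domain error: tracts must be sorted, disjoint and merged")
    }
    if (min(tracts[, 1]) < 0 || max(tracts[, 2]) > L) {
      stop("domain error: tract outside [0, L)")
    }
  }
  len <- interval_lengths(tracts)
  keep <- len >= min_tract_bp
  total <- sum(len[keep])
  structure(
    data.frame(haplotype_id = haplotype_id, generation = generation,
               coverage = total / L, n_tracts = sum(keep),
               total_tract_bp = total),
    class = c("coverage_record", "data.frame")
  )
}

#' Expected autosome to chromosome X archaic haplotype ratio
#'
#' An introgressing class with female fraction `p` carries 2 autosomal
#' haplotypes per individual but only `1 + p` X haplotypes on average, so the
#' expected ratio of introgressing autosomal to X haplotypes is `2 / (1 + p)`:
#' 2 when all introgressors are male, 1 when all are female. The ratio is
#' strictly decreasing in `p`.
#'
#' @param p female fraction of the introgressors, in `[0, 1]` (vectorized).
#' @return `2 / (1 + p)`.
#' @export
expected_haplotype_ratio <- function(p) {
  if (any(p < 0 | p > 1)) stop("domain error: p must lie in [0, 1]")
  2 / (1 + p)
}

#' Bootstrap estimate of the autosome to chromosome X coverage ratio
#'
#' Autosomal and chromosome X simulations are run separately, so there is no
#' natural per-individual pairing; the ratio is a bootstrap construction. Each
#' replicate draws `n_per_draw` coverages with replacement from each pool and
#' takes the ratio of the two means; the estimate is the mean of replicates
#' with an empirical percentile 95% confidence interval.
#'
#' Replicates whose chromosome X resample has mean zero are rejected and
#' redrawn; if more than 10% of replicates are rejected the estimate is
#' flagged unreliable.
#'
#' @param aut_cov,x_cov numeric pools of per-haplotype coverages.
#' @param n_per_draw draws per pool per replicate.
#' @param n_boot number of bootstrap replicates.
#' @param seed optional integer seed.
#' @return Object of class `ratio_estimate`: `mean_ratio`, `ci_low`,
#'   `ci_high`, `n_boot`, `n_per_draw`, `n_rejected`, `unreliable`.
#' @export
bootstrap_ratio <- function(aut_cov, x_cov, n_per_draw = 10000,
                            n_boot = 2000, seed = NULL) {
  stopifnot(length(aut_cov) > 0, length(x_cov) > 0,
            n_per_draw >= 1, n_boot >= 1)
  with_seed(seed, {
    ratios <- numeric(n_boot)
    rejected <- 0L
    max_attempts <- 100L
    for (b in seq_len(n_boot)) {
      r <- NA_real_
      for (a in seq_len(max_attempts)) {
        ma <- mean(aut_cov[sample.int(length(aut_cov), n_per_draw, replace = TRUE)])
        mx <- mean(x_cov[sample.int(length(x_cov), n_per_draw, replace = TRUE)])
        if (mx > 0) {
          r <- ma / mx
          break
        }
        rejected <- rejected + 1L
      }
      if (is.na(r)) {
        stop("bootstrap error: chromosome X resamples persistently have mean 0")
      }
      ratios[b] <- r
    }
    unreliable <- rejected > 0.1 * n_boot
    if (unreliable) {
      warning(sprintf("bootstrap_ratio: %d rejected resamples (> 10%% of n_boot); estimate flagged unreliable",
                      rejected))
    }
    ci <- unname(stats::quantile(ratios, c(0.025, 0.975), type = 7))
    structure(
      list(mean_ratio = mean(ratios), ci_low = ci[1], ci_high = ci[2],
           n_boot = n_boot, n_per_draw = n_per_draw,
           n_rejected = rejected, unreliable = unreliable,
           replicates = ratios),
      class = "ratio_estimate"
    )
  })
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("<ratio_estimate> mean %.4g, 95%% CI [%.4g, %.4g] (%d replicates of %d draws)%s\n",
              x$mean_ratio, x$ci_low, x$ci_high, x$n_boot, x$n_per_draw,
              if (x$unreliable) " [UNRELIABLE]" else ""))
  invisible(x)
}

#' Pearson correlation between introgressor female fraction and coverage
#'
#' Pools per-haplotype coverages across sex-bias scenarios and correlates the
#' scenario's female fraction `p` with coverage.
#'
#' @param p female fraction for each observation.
#' @param coverage per-haplotype coverage for each observation.
#' @return List with `rho`, `pvalue`, `n`.
#' @export
sexbias_coverage_correlation <- function(p, coverage) {
  stopifnot(length(p) == length(coverage))
  if (length(p) < 3) stop("need at least 3 samples")
  if (stats::var(p) == 0 || stats::var(coverage) == 0) {
    stop("undefined-correlation error: zero variance in p or coverage")
  }
  ct <- stats::cor.test(p, coverage, method = "pearson")
  list(rho = unname(ct$estimate), pvalue = ct$p.value, n = length(p))
}

#' Per-generation coverage timecourse summary
#'
#' Mean, variance and percentile bootstrap 95% confidence interval of
#' per-haplotype coverage at each sampled generation.
#'
#' @param records data frame with columns `generation` and `coverage`
#'   (e.g. stacked coverage records from [run_scenario()], possibly pooled
#'   over replicates).
#' @param n_boot bootstrap replicates for the CI of the mean.
#' @param seed optional integer seed.
#' @return Data frame (class `timecourse`) with one row per generation:
#'   `generation`, `n`, `mean_coverage`, `variance_coverage`, `ci_low`,
#'   `ci_high`.
#' @export
timecourse_summary <- function(records, n_boot = 500, seed = NULL) {
  stopifnot(all(c("generation", "coverage") %in% names(records)))
  gens <- sort(unique(records$generation))
  with_seed(seed, {
    rows <- lapply(gens, function(g) {
      x <- records$coverage[records$generation == g]
      if (length(x) == 0) {
        warning(sprintf("empty generation group %s skipped", g))
        return(NULL)
      }
      if (length(x) == 1) {
        return(data.frame(generation = g, n = 1L, mean_coverage = x,
                          variance_coverage = 0, ci_low = x, ci_high = x))
      }
      boots <- vapply(seq_len(n_boot), function(i) {
        mean(x[sample.int(length(x), length(x), replace = TRUE)])
      }, numeric(1))
      ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
      data.frame(generation = g, n = length(x), mean_coverage = mean(x),
                 variance_coverage = stats::var(x) * (length(x) - 1) / length(x),
                 ci_low = ci[1], ci_high = ci[2])
    })
    out <- do.call(rbind, rows)
    class(out) <- c("timecourse", "data.frame")
    out
  })
}

#' Half-decay generation of the coverage timecourse
#'
#' The first sampled generation at which mean coverage has fallen at least
#' halfway from its value in the generation immediately following the pulse
#' (generation 1) to its final value: threshold `(c_1 + c_final) / 2`. If
#' there is no decay (`c_1 <= c_final`) generation 1 is returned with
#' `no_decay = TRUE`. Only sampled generations are considered (no
#' interpolation).
#'
#' @param timecourse a data frame from [timecourse_summary()] whose
#'   generations are counted since the pulse and include generation 1 and a
#'   final generation.
#' @return List with `generation`, `threshold`, `no_decay`.
#' @export
half_decay_generation <- function(timecourse) {
  stopifnot(all(c("generation", "mean_coverage") %in% names(timecourse)))
  tc <- timecourse[order(timecourse$generation), ]
  if (tc$generation[1] != 1) {
    stop("contract error: timecourse must include generation 1 after the pulse")
  }
  c1 <- tc$mean_coverage[1]
  cf <- tc$mean_coverage[nrow(tc)]
  if (c1 <= cf) {
    return(list(generation = 1, threshold = c1, no_decay = TRUE))
  }
  thr <- (c1 + cf) / 2
  hit <- which(tc$mean_coverage <= thr)[1]
  list(generation = tc$generation[hit], threshold = thr, no_decay = FALSE)
}
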