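#' Ingest per-haplotype archaic tract call files
#'
#' Reads tab-separated tract call files (one per haplotype per individual,
#' named `<individual>_hap1.tsv` / `<individual>_hap2.tsv`, with header
#' columns `chrom`, `start`, `end`, `posterior`, `n_support_snps`) into a
#' normalized call table. The `pos1` dialect (1-based, closed intervals, as
#' printed by some HMM callers) is converted to 0-based half-open on
#' ingestion.
#'
#' @param paths character vector of tract files, or a single directory
#'   containing them.
#' @param dialect `"bed0"` (0-based half-open, default) or `"pos1"` (1-based
#'   closed).
#' @return Data frame of class `tract_calls`: `individual_id`,
#'   `haplotype_index`, `chrom`, `start`, `end`, `posterior`,
#'   `n_support_snps`.
#' @export
ingest_tracts <- function(paths, dialect = c("bed0", "pos1")) {
  dialect <- match.arg(dialect)
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "_hap[12]\\.tsv$", full.names = TRUE)
  }
  if (length(paths) == 0) stop("ingestion error: no tract files found")
  base <- basename(paths)
  m <- regmatches(base, regexec("^(.*)_hap([12])\\.tsv$", base))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    stop("ingestion error: file name(s) not matching <individual>_hap<1|2>.tsv: ",
         paste(base[bad], collapse = ", "))
  }
  ind <- vapply(m, `[`, "", 2)
  hap <- as.integer(vapply(m, `[`, "", 3))
  got <- split(hap, ind)
  incomplete <- names(got)[!vapply(got, function(h) all(1:2 %in% h), logical(1))]
  if (length(incomplete) > 0) {
    stop("ingestion error: missing haplotype file for individual(s): ",
         paste(incomplete, collapse = ", "))
  }
  pieces <- lapply(seq_along(paths), function(i) {
    d <- utils::read.table(paths[i], header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "posterior", "n_support_snps")
    if (!all(need %in% names(d))) {
      stop("parse error: ", paths[i], " lacks columns ",
           paste(setdiff(need, names(d)), collapse = ", "))
    }
    if (nrow(d) == 0) {
      return(data.frame(individual_id = character(0),
                        haplotype_index = integer(0), chrom = character(0),
                        start = numeric(0), end = numeric(0),
                        posterior = numeric(0), n_support_snps = integer(0)))
    }
    if (dialect == "pos1") d$start <- d$start - 1
    if (any(d$start < 0)) {
      stop("parse error: negative coordinate in ", paths[i])
    }
    if (any(d$end <= d$start)) {
      stop("parse error: end <= start in ", paths[i])
    }
    if (any(d$posterior < 0 | d$posterior > 1)) {
      stop("parse error: posterior outside [0, 1] in ", paths[i])
    }
    data.frame(individual_id = ind[i], haplotype_index = hap[i],
               chrom = as.character(d$chrom), start = as.numeric(d$start),
               end = as.numeric(d$end), posterior = as.numeric(d$posterior),
               n_support_snps = as.integer(d$n_support_snps))
  })
  out <- do.call(rbind, pieces)
  class(out) <- c("tract_calls", "data.frame")
  out
}

#' Filter tract calls
#'
#' Applies the call-quality filters: calls with posterior probability below
#' `min_posterior` are removed (the boundary is kept: `posterior < 0.8` goes,
#' `0.8` stays); calls supported by zero archaic-matching SNPs are removed
#' when `require_snp_support` is on; chromosome X calls overlapping the
#' pseudoautosomal region by any amount are removed whole (no trimming).
#'
#' @param calls a `tract_calls` data frame.
#' @param min_posterior posterior threshold (strict `<` removal).
#' @param require_snp_support drop calls with `n_support_snps == 0`.
#' @param par optional PAR interval `c(start, end)` on `x_chrom`.
#' @param x_chrom chromosome label treated as X.
#' @return Filtered `tract_calls`.
#' @export
filter_tracts <- function(calls, min_posterior = 0.8,
                          require_snp_support = TRUE, par = NULL,
                          x_chrom = "chrX") {
  keep <- calls$posterior >= min_posterior
  if (require_snp_support) keep <- keep & calls$n_support_snps > 0
  if (!is.null(par)) {
    overlaps_par <- calls$chrom == x_chrom &
      calls$start < par[2] & calls$end > par[1]
    keep <- keep & !overlaps_par
  }
  out <- calls[keep, , drop = FALSE]
  class(out) <- c("tract_calls", "data.frame")
  out
}

merged_bp <- function(start, end) {
  if (length(start) == 0) return(0)
  sum(interval_lengths(merge_intervals(cbind(start, end))))
}

#' Per-individual per-bp archaic coverage rates
#'
#' For each individual, tract lengths are merged per haplotype and chromosome
#' (so duplicated or overlapping calls never double-count), then summed across
#' both haplotypes and divided by twice the relevant chromosome length:
#' `aut_rate = sum(aut bp) / (2 * sum(autosome lengths))` and
#' `chrx_rate = sum(X bp) / (2 * (L_X - PAR length))`. The within-individual
#' ratio `aut_rate / chrx_rate` is `NA` (undefined) when `chrx_rate` is zero;
#' such individuals are kept for rate summaries but drop out of ratio
#' summaries.
#'
#' @param calls filtered `tract_calls`.
#' @param chrom_lengths data frame with columns `chrom`, `length`.
#' @param par optional PAR interval on `x_chrom`, excluded from the X
#'   denominator.
#' @param x_chrom chromosome label treated as X.
#' @param groups optional data frame `individual_id`, `group` to annotate.
#' @return Data frame of class `individual_coverage`: `individual_id`,
#'   (`group`,) `aut_rate`, `chrx_rate`, `ratio`.
#' @export
per_bp_rate <- function(calls, chrom_lengths, par = NULL, x_chrom = "chrX",
                        groups = NULL) {
  stopifnot(all(c("chrom", "length") %in% names(chrom_lengths)))
  aut_len <- sum(chrom_lengths$length[chrom_lengths$chrom != x_chrom])
  x_len <- sum(chrom_lengths$length[chrom_lengths$chrom == x_chrom])
  par_len <- if (is.null(par)) 0 else par[2] - par[1]
  x_denom <- 2 * (x_len - par_len)
  if (aut_len <= 0 || x_denom <= 0) {
    stop("configuration error: non-positive denominator from chrom_lengths/par")
  }
  ids <- unique(calls$individual_id)
  rows <- lapply(ids, function(id) {
    d <- calls[calls$individual_id == id, ]
    aut_bp <- 0
    x_bp <- 0
    for (h in unique(d$haplotype_index)) {
      for (ch in unique(d$chrom[d$haplotype_index == h])) {
        sel <- d$haplotype_index == h & d$chrom == ch
        bp <- merged_bp(d$start[sel], d$end[sel])
        if (ch == x_chrom) x_bp <- x_bp + bp else aut_bp <- aut_bp + bp
      }
    }
    data.frame(individual_id = id, aut_rate = aut_bp / (2 * aut_len),
               chrx_rate = x_bp / x_denom)
  })
  out <- do.call(rbind, rows)
  out$ratio <- ifelse(out$chrx_rate > 0, out$aut_rate / out$chrx_rate, NA_real_)
  if (!is.null(groups)) {
    out$group <- groups$group[match(out$individual_id, groups$individual_id)]
    out <- out[, c("individual_id", "group", "aut_rate", "chrx_rate", "ratio")]
  }
  class(out) <- c("individual_coverage", "data.frame")
  out
}

#' Remove outlier individuals
#'
#' Drops individuals whose aut:chrX coverage ratio exceeds `max_ratio` or
#' whose autosomal coverage rate exceeds `max_aut_rate` (strict inequalities:
#' ratio exactly 50 and rate exactly 0.1 are retained).
#'
#' @param individuals an `individual_coverage` data frame.
#' @param max_ratio,max_aut_rate exclusion thresholds.
#' @return Filtered `individual_coverage`.
#' @export
exclude_outliers <- function(individuals, max_ratio = 50, max_aut_rate = 0.1) {
  drop <- (!is.na(individuals$ratio) & individuals$ratio > max_ratio) |
    individuals$aut_rate > max_aut_rate
  out <- individuals[!drop, , drop = FALSE]
  class(out) <- c("individual_coverage", "data.frame")
  out
}

boot_ci <- function(x, n_boot) {
  if (length(x) < 2) return(c(NA_real_, NA_real_))
  b <- vapply(seq_len(n_boot), function(i) {
    mean(x[sample.int(length(x), length(x), replace = TRUE)])
  }, numeric(1))
  unname(stats::quantile(b, c(0.025, 0.975)))
}

#' Group-level coverage summaries
#'
#' Per-group mean autosomal rate, chromosome X rate and within-individual
#' aut:chrX ratio (over individuals with a defined ratio), with percentile
#' bootstrap 95% confidence intervals over individuals, plus ascending rank
#' orderings of groups by each of the three metrics. Singleton groups get
#' means only (CIs `NA`).
#'
#' @param individuals an `individual_coverage` data frame with a `group`
#'   column.
#' @param n_boot bootstrap replicates.
#' @param seed optional integer seed.
#' @return List with `summary` (one row per group) and `rankings` (list of
#'   group labels in ascending order by `chrx_rate`, `aut_rate`, `ratio`).
#' @export
group_summary <- function(individuals, n_boot = 2000, seed = NULL) {
  stopifnot("group" %in% names(individuals))
  with_seed(seed, {
    groups <- sort(unique(individuals$group))
    rows <- lapply(groups, function(g) {
      d <- individuals[individuals$group == g, ]
      r <- d$ratio[!is.na(d$ratio)]
      ci_a <- boot_ci(d$aut_rate, n_boot)
      ci_x <- boot_ci(d$chrx_rate, n_boot)
      ci_r <- boot_ci(r, n_boot)
      data.frame(group = g, n = nrow(d),
                 aut_rate = mean(d$aut_rate),
                 aut_ci_low = ci_a[1], aut_ci_high = ci_a[2],
                 chrx_rate = mean(d$chrx_rate),
                 chrx_ci_low = ci_x[1], chrx_ci_high = ci_x[2],
                 n_ratio = length(r),
                 ratio = if (length(r) > 0) mean(r) else NA_real_,
                 ratio_ci_low = ci_r[1], ratio_ci_high = ci_r[2])
    })
    s <- do.call(rbind, rows)
    rankings <- list(
      chrx_rate = s$group[order(s$chrx_rate)],
      aut_rate = s$group[order(s$aut_rate)],
      ratio = s$group[order(s$ratio)]
    )
    list(summary = s, rankings = rankings)
  })
}

#' Pairwise Welch's t-tests with Bonferroni correction
#'
#' Welch's unequal-variance two-sided t-test for every pair of groups on the
#' chosen metric. The significance threshold is `alpha / n_pairs` (Bonferroni;
#' 4 groups give 6 pairs and a threshold of 0.05 / 6 = 0.00833...). Pairs
#' where both groups are constant with equal means get `p = 1` by convention.
#'
#' @param individuals an `individual_coverage` data frame with `group`.
#' @param metric `"aut_rate"`, `"chrx_rate"` or `"ratio"`.
#' @param alpha family-wise significance level.
#' @return List with `tests` (data frame: `group1`, `group2`, `t`, `df`, `p`,
#'   `significant`) and `threshold`.
#' @export
pairwise_welch <- function(individuals, metric = c("aut_rate", "chrx_rate", "ratio"),
                           alpha = 0.05) {
  metric <- match.arg(metric)
  stopifnot("group" %in% names(individuals))
  groups <- sort(unique(individuals$group))
  if (length(groups) < 2) stop("need at least 2 groups")
  vals <- lapply(groups, function(g) {
    v <- individuals[[metric]][individuals$group == g]
    v <- v[!is.na(v)]
    if (length(v) < 2) stop("group ", g, " has fewer than 2 usable values")
    v
  })
  names(vals) <- groups
  pairs <- utils::combn(groups, 2)
  threshold <- alpha / ncol(pairs)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    x <- vals[[pairs[1, i]]]
    y <- vals[[pairs[2, i]]]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      tt <- list(statistic = if (mean(x) == mean(y)) 0 else Inf,
                 parameter = NA_real_,
                 p.value = if (mean(x) == mean(y)) 1 else 0)
    } else {
      ht <- stats::t.test(x, y, var.equal = FALSE)
      tt <- list(statistic = unname(ht$statistic),
                 parameter = unname(ht$parameter), p.value = ht$p.value)
    }
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               t = tt$statistic, df = tt$parameter, p = tt$p.value,
               significant = tt$p.value < threshold)
  })
  list(tests = do.call(rbind, rows), threshold = threshold, metric = metric)
}

#' Median aut:chrX ratio of a published-estimate table
#'
#' Summarizes a table of published archaic-coverage estimates (one row per
#' group/method) by the median autosome to chromosome X per-bp coverage
#' ratio, optionally within a subset.
#'
#' @param estimates data frame with either a `ratio` column or `aut_rate` and
#'   `chrx_rate` columns.
#' @param subset optional logical vector selecting rows.
#' @return List with `median_ratio` and `n`.
#' @export
published_ratio_summary <- function(estimates, subset = NULL) {
  if (!"ratio" %in% names(estimates)) {
    stopifnot(all(c("aut_rate", "chrx_rate") %in% names(estimates)))
    estimates$ratio <- estimates$aut_rate / estimates$chrx_rate
  }
  if (!is.null(subset)) estimates <- estimates[subset, , drop = FALSE]
  r <- estimates$ratio[is.finite(estimates$ratio)]
  if (length(r) == 0) stop("no finite ratios to summarize")
  list(median_ratio = stats::median(r), n = length(r))
}
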