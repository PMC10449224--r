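#' Specification for a synthetic tract-call cohort
#'
#' Describes a cohort whose per-individual archaic tract calls have planted
#' group-level per-bp coverage rates, gamma-distributed tract lengths, a
#' posterior-score mixture with a configurable mass below the 0.8 filter
#' threshold, and a configurable probability of zero SNP support. Tracts that
#' pass all filters carry the planted coverage exactly (up to integer
#' rounding); filter-failing "decoy" tracts are added on top so the filters
#' have something to remove. Core chromosome X tracts avoid the PAR; decoys
#' may overlap it.
#'
#' @param groups data frame with columns `group`, `n` (individuals),
#'   `aut_rate`, `chrx_rate` (planted post-filter per-bp rates, in (0, 0.1)),
#'   and optionally `rate_cv` (between-individual coefficient of variation of
#'   overall coverage scale, default 0.1) and `ratio_cv` (extra
#'   within-individual noise on the chrX side, default 0.05).
#' @param chrom_lengths data frame `chrom`, `length`; must contain `x_chrom`.
#' @param par PAR interval on `x_chrom` (excluded from planted X coverage and
#'   from the pipeline denominator).
#' @param x_chrom chromosome label treated as X.
#' @param mean_tract_len mean tract length in bp.
#' @param tract_len_shape gamma shape of tract lengths.
#' @param posterior_below_frac fraction of total tract bp carried by decoy
#'   tracts with posterior below 0.8.
#' @param snp_zero_prob fraction of decoy tracts that instead fail by zero
#'   SNP support.
#' @param seed integer seed; generation is a pure function of spec + seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups,
                        chrom_lengths = data.frame(
                          chrom = c("chr1", "chr2", "chrX"),
                          length = c(8e7, 7e7, 1.5e8)),
                        par = c(0, 3e6), x_chrom = "chrX",
                        mean_tract_len = 5e4, tract_len_shape = 2,
                        posterior_below_frac = 0.1, snp_zero_prob = 0.3,
                        seed = 1L) {
  stopifnot(all(c("group", "n", "aut_rate", "chrx_rate") %in% names(groups)),
            all(groups$aut_rate > 0 & groups$aut_rate < 0.1),
            all(groups$chrx_rate >= 0 & groups$chrx_rate < 0.1),
            x_chrom %in% chrom_lengths$chrom,
            posterior_below_frac >= 0, posterior_below_frac < 1)
  if (!"rate_cv" %in% names(groups)) groups$rate_cv <- 0.1
  if (!"ratio_cv" %in% names(groups)) groups$ratio_cv <- 0.05
  structure(list(groups = groups, chrom_lengths = chrom_lengths, par = par,
                 x_chrom = x_chrom, mean_tract_len = mean_tract_len,
                 tract_len_shape = tract_len_shape,
                 posterior_below_frac = posterior_below_frac,
                 snp_zero_prob = snp_zero_prob, seed = as.integer(seed)),
            class = "cohort_spec")
}

# gamma tract lengths that sum to target_bp exactly (last one trimmed)
draw_tract_lengths <- function(target_bp, mean_len, shape) {
  if (target_bp <= 0) return(numeric(0))
  lens <- numeric(0)
  while (sum(lens) < target_bp) {
    k <- max(8, ceiling((target_bp - sum(lens)) / mean_len) + 8)
    lens <- c(lens, pmax(1, round(stats::rgamma(k, shape = shape,
                                                scale = mean_len / shape))))
  }
  cum <- cumsum(lens)
  n <- which(cum >= target_bp)[1]
  lens <- lens[seq_len(n)]
  lens[n] <- lens[n] - (cum[n] - target_bp)
  lens[lens >= 1]
}

# place lengths without overlap in [lo, hi) via uniform spacings
place_tracts <- function(lens, lo, hi) {
  n <- length(lens)
  if (n == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  free <- (hi - lo) - sum(lens)
  if (free < 0) {
    stop("configuration error: planted rate unreachable, tracts exceed chromosome")
  }
  u <- sort(stats::runif(n))
  gaps <- floor(diff(c(0, u)) * free)
  starts <- lo + cumsum(gaps) + cumsum(c(0, lens[-n]))
  cbind(start = starts, end = starts + lens)
}

#' Generate a synthetic cohort of tract-call files
#'
#' Writes per-individual per-haplotype tract files, a group metadata table, a
#' chromosome-lengths table, a PAR BED file and a ground-truth table of
#' planted per-individual rates. Output is byte-identical for identical spec
#' and seed. The files match [ingest_tracts()]'s input contract exactly.
#'
#' @param spec a [cohort_spec].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a manifest list: `tract_files`, `metadata`,
#'   `chrom_lengths`, `par_bed`, `truth` (data frame of planted
#'   per-individual rates).
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cl <- spec$chrom_lengths
  auts <- cl[cl$chrom != spec$x_chrom, ]
  x_len <- cl$length[cl$chrom == spec$x_chrom]
  par_len <- if (is.null(spec$par)) 0 else spec$par[2] - spec$par[1]
  # feasibility: planted bp must fit on the chromosomes
  worst <- max(spec$groups$aut_rate) * (1 + 3 * max(spec$groups$rate_cv))
  if (worst / (1 - spec$posterior_below_frac) > 0.5) {
    stop("configuration error: planted rates unreachable at these settings")
  }

  with_seed(spec$seed, {
    files <- character(0)
    truth <- list()
    meta <- list()
    for (gi in seq_len(nrow(spec$groups))) {
      g <- spec$groups[gi, ]
      sdlog <- sqrt(log(1 + g$rate_cv^2))
      for (ii in seq_len(g$n)) {
        id <- sprintf("%s_%03d", g$group, ii)
        scale_i <- stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        x_noise <- stats::rlnorm(1, meanlog = -log(1 + g$ratio_cv^2) / 2,
                                 sdlog = sqrt(log(1 + g$ratio_cv^2)))
        true_aut <- g$aut_rate * scale_i
        true_x <- g$chrx_rate * scale_i * x_noise
        truth[[id]] <- data.frame(individual_id = id, group = g$group,
                                  true_aut_rate = true_aut,
                                  true_chrx_rate = true_x)
        meta[[id]] <- data.frame(individual_id = id, group = g$group)
        for (h in 1:2) {
          rows <- list()
          # core (filter-passing) tracts per chromosome
          gen_core <- function(chrom, lo, hi, target) {
            pos <- place_tracts(
              draw_tract_lengths(target, spec$mean_tract_len,
                                 spec$tract_len_shape), lo, hi)
            if (nrow(pos) == 0) return(NULL)
            data.frame(chrom = chrom, start = pos[, 1], end = pos[, 2],
                       posterior = stats::runif(nrow(pos), 0.8, 1),
                       n_support_snps = 1L + stats::rpois(nrow(pos), 2))
          }
          # decoy (filter-failing) tracts: fraction q of total bp pre-filter
          gen_decoy <- function(chrom, lo, hi, core_bp) {
            q <- spec$posterior_below_frac
            if (q <= 0 || core_bp <= 0) return(NULL)
            target <- round(core_bp * q / (1 - q))
            pos <- place_tracts(
              draw_tract_lengths(target, spec$mean_tract_len,
                                 spec$tract_len_shape), lo, hi)
            if (nrow(pos) == 0) return(NULL)
            fail_snp <- stats::runif(nrow(pos)) < spec$snp_zero_prob
            data.frame(chrom = chrom, start = pos[, 1], end = pos[, 2],
                       posterior = ifelse(fail_snp,
                                          stats::runif(nrow(pos), 0.8, 1),
                                          stats::runif(nrow(pos), 0.4, 0.7999)),
                       n_support_snps = ifelse(fail_snp, 0L,
                                               1L + stats::rpois(nrow(pos), 2)))
          }
          bp_of <- function(d) if (is.null(d)) 0 else sum(d$end - d$start)
          for (ai in seq_len(nrow(auts))) {
            # per haplotype, per autosome: planted rate times that length
            target <- round(true_aut * auts$length[ai])
            core <- gen_core(auts$chrom[ai], 0, auts$length[ai], target)
            rows <- c(rows, list(core),
                      list(gen_decoy(auts$chrom[ai], 0, auts$length[ai],
                                     bp_of(core))))
          }
          x_lo <- if (!is.null(spec$par) && spec$par[1] == 0) spec$par[2] else 0
          x_target <- round(true_x * (x_len - par_len))
          core_x <- gen_core(spec$x_chrom, x_lo, x_len, x_target)
          rows <- c(rows, list(core_x),
                    list(gen_decoy(spec$x_chrom, 0, x_len, bp_of(core_x))))
          d <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
          path <- file.path(out_dir, sprintf("%s_hap%d.tsv", id, h))
          write_tract_file(d, path)
          files <- c(files, path)
        }
      }
    }
    meta <- do.call(rbind, meta)
    truth <- do.call(rbind, truth)
    meta_path <- file.path(out_dir, "metadata.tsv")
    utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cl_path <- file.path(out_dir, "chrom_lengths.tsv")
    utils::write.table(
      data.frame(chrom = cl$chrom,
                 length = format(cl$length, scientific = FALSE, trim = TRUE)),
      cl_path, sep = "\t", quote = FALSE, row.names = FALSE)
    par_path <- file.path(out_dir, "par.bed")
    writeLines(sprintf("%s\t%s\t%s", spec$x_chrom,
                       format(spec$par[1], scientific = FALSE, trim = TRUE),
                       format(spec$par[2], scientific = FALSE, trim = TRUE)),
               par_path)
    truth_path <- file.path(out_dir, "truth.tsv")
    utils::write.table(
      data.frame(truth[, 1:2],
                 true_aut_rate = sprintf("%.10g", truth$true_aut_rate),
                 true_chrx_rate = sprintf("%.10g", truth$true_chrx_rate)),
      truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(list(tract_files = files, metadata = meta_path,
                   chrom_lengths = cl_path, par_bed = par_path,
                   truth = truth, truth_path = truth_path))
  })
}

write_tract_file <- function(d, path) {
  if (is.null(d) || nrow(d) == 0) {
    writeLines("chrom\tstart\tend\tposterior\tn_support_snps", path)
    return(invisible(path))
  }
  d <- d[order(d$chrom, d$start), ]
  out <- data.frame(chrom = d$chrom,
                    start = format(d$start, scientific = FALSE, trim = TRUE),
                    end = format(d$end, scientific = FALSE, trim = TRUE),
                    posterior = sprintf("%.6f", d$posterior),
                    n_support_snps = d$n_support_snps)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate neutral tract lengths under the exponential model
#'
#' Draws `n` tract lengths from an exponential with rate `r * t` (truncated to
#' `[1, L)`), and places them uniformly without overlap on a chromosome of
#' length `L`. This is the sampling counterpart of
#' [neutral_length_density()].
#'
#' @param n number of tracts.
#' @param r per-bp recombination rate per generation.
#' @param t generations since the pulse.
#' @param L chromosome length in bp.
#' @param seed optional integer seed.
#' @param inheritance `"autosomal"` or `"chrX"` (chrX uses the 2/3 effective
#'   rate).
#' @return Two-column matrix of tract intervals.
#' @export
generate_neutral_tracts <- function(n, r, t, L, seed = NULL,
                                    inheritance = c("autosomal", "chrX")) {
  inheritance <- match.arg(inheritance)
  stopifnot(n >= 0, r > 0, t > 0, L > 1)
  if (n == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  r_eff <- if (inheritance == "chrX") (2 / 3) * r else r
  with_seed(seed, {
    lens <- pmin(pmax(round(stats::rexp(n, rate = r_eff * t)), 1), L - 1)
    if (sum(lens) > L) {
      stop("placement error: total requested tract length exceeds L")
    }
    place_tracts(lens, 0, L)
  })
}
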