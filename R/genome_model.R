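#' Chromosome map: length, exons, recombination landscape, inheritance mode
#'
#' A `chromosome_map` describes the simulated chromosome: its length in base
#' pairs, the exon intervals in which deleterious mutations arise, a piecewise
#' recombination-rate map tiling the chromosome, the inheritance mode
#' (autosomal or X-linked), and an optional pseudoautosomal region (PAR). All
#' coordinates are 0-based, half-open (BED convention).
#'
#' The PAR is never simulated; it exists only for the empirical pipeline,
#' which removes chromosome X tract calls overlapping it and excludes its
#' length from the per-bp denominator.
#'
#' @param length_bp chromosome length in base pairs.
#' @param exons two-column matrix of exon intervals `[start, end)`;
#'   overlapping or adjacent intervals are merged.
#' @param recomb data frame or matrix with columns `start`, `end`, `rate`
#'   (per-bp recombination probability per generation); pieces must tile
#'   `[0, length_bp)` exactly with non-negative rates.
#' @param inheritance `"autosomal"` or `"chrX"`.
#' @param name label for the chromosome.
#' @param par optional length-2 vector: the PAR interval `[start, end)`.
#' @return An object of class `chromosome_map`.
#' @export
chromosome_map <- function(length_bp, exons, recomb,
                           inheritance = c("autosomal", "chrX"),
                           name = "chr_sim", par = NULL) {
  inheritance <- match.arg(inheritance)
  stopifnot(is.numeric(length_bp), length_bp > 0)
  exons <- merge_intervals(exons)
  if (nrow(exons) > 0 && (min(exons[, 1]) < 0 || max(exons[, 2]) > length_bp)) {
    stop("bounds error: exon interval outside [0, length_bp)")
  }
  recomb <- as.data.frame(recomb)
  names(recomb)[1:3] <- c("start", "end", "rate")
  recomb <- recomb[order(recomb$start), , drop = FALSE]
  if (any(recomb$rate < 0)) stop("recombination rates must be >= 0")
  tiles <- nrow(recomb) > 0 &&
    recomb$start[1] == 0 &&
    recomb$end[nrow(recomb)] == length_bp &&
    (nrow(recomb) == 1 || all(recomb$start[-1] == recomb$end[-nrow(recomb)]))
  if (!tiles) {
    stop("coverage error: recombination pieces do not tile [0, length_bp) exactly")
  }
  if (!is.null(par)) {
    stopifnot(length(par) == 2, par[1] >= 0, par[2] > par[1], par[2] <= length_bp)
  }
  structure(
    list(name = name, length_bp = as.numeric(length_bp),
         inheritance = inheritance, exons = exons,
         recomb = recomb[, c("start", "end", "rate")], par = par),
    class = "chromosome_map"
  )
}

#' @export
print.chromosome_map <- function(x, ...) {
  cat(sprintf(
    "<chromosome_map> %s: %.3g bp, %s inheritance\n  %d exons (%.3g bp, %.2f%%), %d recombination pieces (mean rate %.3g /bp/gen)%s\n",
    x$name, x$length_bp, x$inheritance, nrow(x$exons),
    sum(interval_lengths(x$exons)),
    100 * sum(interval_lengths(x$exons)) / x$length_bp,
    nrow(x$recomb), mean_recombination_rate(x),
    if (is.null(x$par)) "" else sprintf(", PAR [%g, %g)", x$par[1], x$par[2])
  ))
  invisible(x)
}

read_bed3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  bad <- which(n < 3)
  if (length(bad) > 0) {
    stop(sprintf("parse error: malformed BED line %d in %s", bad[1], path))
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("parse error: malformed BED line %d in %s",
                 which(is.na(start) | is.na(end))[1], path))
  }
  data.frame(chrom = vapply(fields, `[`, "", 1), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Load a chromosome map from BED files
#'
#' Exons come from a standard 3+ column BED file; the recombination map from a
#' 4-column BED-like file (`chrom`, `start`, `end`, `rate`). Overlapping exons
#' are merged; recombination pieces must tile the chromosome exactly.
#'
#' @param exon_bed path to the exon BED file.
#' @param recomb_bed path to the recombination-map file.
#' @param length_bp chromosome length in bp.
#' @param inheritance `"autosomal"` or `"chrX"`.
#' @param par_bed optional single-interval BED file giving the PAR.
#' @inheritParams chromosome_map
#' @return A [chromosome_map].
#' @export
load_chromosome_map <- function(exon_bed, recomb_bed, length_bp,
                                inheritance = c("autosomal", "chrX"),
                                name = "chr_sim", par_bed = NULL) {
  ex <- read_bed3(exon_bed)
  rc <- read_bed3(recomb_bed)
  lines <- readLines(recomb_bed)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) > 0 && any(vapply(fields, length, integer(1)) < 4)) {
    stop(sprintf("parse error: malformed BED line %d in %s (need 4 columns)",
                 which(vapply(fields, length, integer(1)) < 4)[1], recomb_bed))
  }
  rc$rate <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4)))
  if (anyNA(rc$rate)) {
    stop(sprintf("parse error: non-numeric rate on line %d in %s",
                 which(is.na(rc$rate))[1], recomb_bed))
  }
  par <- NULL
  if (!is.null(par_bed)) {
    pb <- read_bed3(par_bed)
    if (nrow(pb) > 0) par <- c(pb$start[1], pb$end[1])
  }
  chromosome_map(length_bp, as.matrix(ex[, c("start", "end")]),
                 rc[, c("start", "end", "rate")], inheritance,
                 name = name, par = par)
}

#' Write a chromosome map back to BED files
#'
#' Inverse of [load_chromosome_map()]; `load_chromosome_map(write(...))`
#' round-trips exactly.
#'
#' @param map a [chromosome_map].
#' @param exon_bed,recomb_bed output paths.
#' @return Invisibly, the map.
#' @export
write_chromosome_map <- function(map, exon_bed, recomb_bed) {
  ex <- data.frame(chrom = map$name,
                   start = format(map$exons[, 1], scientific = FALSE, trim = TRUE),
                   end = format(map$exons[, 2], scientific = FALSE, trim = TRUE))
  utils::write.table(ex, exon_bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  rc <- data.frame(chrom = map$name,
                   start = format(map$recomb$start, scientific = FALSE, trim = TRUE),
                   end = format(map$recomb$end, scientific = FALSE, trim = TRUE),
                   rate = format(map$recomb$rate, digits = 17))
  utils::write.table(rc, recomb_bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(map)
}

#' Synthesize a chromosome map
#'
#' Generates a reproducible chromosome structure when no external maps are
#' supplied: exons alternate with intergenic blocks (geometric lengths,
#' rescaled so the exonic total hits `exon_fraction * length_bp` exactly up to
#' rounding), and a piecewise recombination map whose length-weighted mean
#' rate equals `mean_recomb_rate` exactly (piece rates are lognormal
#' perturbations renormalized to the target mean).
#'
#' @param length_bp chromosome length in bp.
#' @param exon_fraction fraction of the chromosome covered by exons (0-1).
#' @param mean_exon_len mean exon length in bp.
#' @param mean_recomb_rate length-weighted mean recombination rate
#'   (per bp per generation).
#' @param n_rate_pieces number of recombination-map pieces; 1 gives a uniform
#'   map with rate exactly `mean_recomb_rate`.
#' @param rate_sdlog lognormal sd (log scale) of piece-rate variation.
#' @param seed integer seed; identical seeds give identical maps.
#' @inheritParams chromosome_map
#' @return A [chromosome_map].
#' @export
synthesize_chromosome_map <- function(length_bp, exon_fraction = 0.015,
                                      mean_exon_len = 160,
                                      mean_recomb_rate = 1e-8,
                                      n_rate_pieces = 50, rate_sdlog = 0.5,
                                      seed = 1L,
                                      inheritance = c("autosomal", "chrX"),
                                      name = "chr_sim", par = NULL) {
  inheritance <- match.arg(inheritance)
  stopifnot(exon_fraction > 0, exon_fraction < 1, mean_recomb_rate > 0,
            n_rate_pieces >= 1)
  target_exonic <- exon_fraction * length_bp
  if (target_exonic < mean_exon_len) {
    stop("configuration error: exon_fraction * length_bp < mean_exon_len")
  }
  with_seed(seed, {
    n_ex <- max(1L, as.integer(round(target_exonic / mean_exon_len)))
    len <- stats::rgeom(n_ex, prob = 1 / mean_exon_len) + 1
    len <- pmax(1, round(len * target_exonic / sum(len)))
    gap_total <- length_bp - sum(len)
    if (gap_total < 0) {
      stop("configuration error: exonic bp exceed chromosome length")
    }
    # distribute intergenic bp over n_ex + 1 gaps via uniform spacings;
    # floor keeps the running total within the chromosome
    u <- sort(stats::runif(n_ex))
    gaps <- floor(diff(c(0, u, 1)) * gap_total)
    starts <- cumsum(c(0, len[-n_ex])) + cumsum(gaps[seq_len(n_ex)])
    exons <- cbind(start = starts, end = starts + len)

    if (n_rate_pieces == 1) {
      recomb <- data.frame(start = 0, end = length_bp, rate = mean_recomb_rate)
    } else {
      cuts <- sort(stats::runif(n_rate_pieces - 1, 1, length_bp - 1))
      cuts <- unique(round(cuts))
      edges <- c(0, cuts, length_bp)
      raw <- stats::rlnorm(length(edges) - 1, meanlog = 0, sdlog = rate_sdlog)
      piece_len <- diff(edges)
      raw <- raw * mean_recomb_rate * length_bp / sum(raw * piece_len)
      recomb <- data.frame(start = edges[-length(edges)], end = edges[-1],
                           rate = raw)
    }
    chromosome_map(length_bp, exons, recomb, inheritance, name = name,
                   par = par)
  })
}

#' Length-weighted mean recombination rate
#'
#' @param map a [chromosome_map].
#' @param window optional interval `c(start, end)` (0-based half-open) over
#'   which to average; defaults to the whole chromosome.
#' @return Mean per-bp recombination rate over the window.
#' @export
mean_recombination_rate <- function(map, window = NULL) {
  stopifnot(inherits(map, "chromosome_map"))
  if (is.null(window)) window <- c(0, map$length_bp)
  if (window[2] <= window[1] || window[1] < 0 || window[2] > map$length_bp) {
    stop("domain error: empty or out-of-bounds window")
  }
  ov_start <- pmax(map$recomb$start, window[1])
  ov_end <- pmin(map$recomb$end, window[2])
  ov <- pmax(0, ov_end - ov_start)
  sum(map$recomb$rate * ov) / (window[2] - window[1])
}
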