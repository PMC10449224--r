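#' Tract-length spectrum
#'
#' Histogram of archaic tract lengths in contiguous bins of `bin_width` bp
#' (default 3000 bp) starting at 0. Counts sum to the number of tracts.
#'
#' @param lengths tract lengths in bp, or a two-column tract matrix.
#' @param bin_width bin width in bp (> 0).
#' @return Object of class `tract_spectrum`: `bin_edges` (length
#'   `n_bins + 1`), `counts`, `n`.
#' @export
length_spectrum <- function(lengths, bin_width = 3000) {
  if (bin_width <= 0) stop("domain error: bin_width must be > 0")
  lengths <- tract_lengths(lengths)
  if (length(lengths) == 0) {
    return(structure(list(bin_edges = c(0, bin_width), counts = 0L, n = 0L),
                     class = "tract_spectrum"))
  }
  n_bins <- max(1, ceiling(max(lengths) / bin_width))
  edges <- seq(0, n_bins * bin_width, by = bin_width)
  idx <- pmin(floor(lengths / bin_width) + 1, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges, counts = counts, n = length(lengths)),
            class = "tract_spectrum")
}

tract_lengths <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    return(x[, 2] - x[, 1])
  }
  as.numeric(x)
}

#' Neutral exponential model for tract lengths
#'
#' After a single pulse, neutral admixture tracts are approximately
#' exponential in length with rate `r_eff * t`, where `t` is generations since
#' the pulse and `r_eff` the effective per-bp recombination rate: the mean map
#' rate for autosomes, and 2/3 of it for chromosome X (recombination happens
#' only in female meiosis, and 2 of every 3 transmitted X copies pass through
#' a female). Chromosome X tracts are therefore expected to be 1.5 times
#' longer than autosomal tracts at equal `r` and `t`.
#'
#' @param length tract length(s) in bp.
#' @param mean_rate mean recombination rate per bp per generation (> 0).
#' @param t generations since the pulse (> 0).
#' @param inheritance `"autosomal"` or `"chrX"`.
#' @return Density values `lambda * exp(-lambda * length)`.
#' @export
neutral_length_density <- function(length, mean_rate, t,
                                   inheritance = c("autosomal", "chrX")) {
  inheritance <- match.arg(inheritance)
  if (mean_rate <= 0 || t <= 0) stop("domain error: mean_rate and t must be > 0")
  r_eff <- if (inheritance == "chrX") (2 / 3) * mean_rate else mean_rate
  stats::dexp(length, rate = r_eff * t)
}

#' Length-weighted mean recombination rate within a tract
#'
#' @param tract length-2 vector `c(start, end)` (0-based half-open).
#' @param map a [chromosome_map].
#' @return Mean per-bp rate over the tract.
#' @export
tract_mean_recomb <- function(tract, map) {
  if (tract[2] <= tract[1]) stop("domain error: zero-length tract")
  mean_recombination_rate(map, window = tract)
}

#' Coverage share of the longest tracts
#'
#' Share of total tract base pairs contained in the `ceiling(top_fraction *
#' n)` longest tracts (ties at the cutoff resolved by including tied tracts up
#' to the count). `share_top + share_rest = 1` exactly.
#'
#' @param lengths tract lengths in bp, or a two-column tract matrix.
#' @param top_fraction fraction of tracts counted as "longest", in `(0, 1)`.
#' @return List with `share_top`, `share_rest`, `n_top`, `cutoff_bp`.
#' @export
top_fraction_share <- function(lengths, top_fraction = 0.01) {
  lengths <- tract_lengths(lengths)
  if (length(lengths) == 0) stop("domain error: empty tract set")
  if (top_fraction <= 0 || top_fraction >= 1) {
    stop("domain error: top_fraction must be in (0, 1)")
  }
  k <- ceiling(top_fraction * length(lengths))
  srt <- sort(lengths, decreasing = TRUE)
  share_top <- sum(srt[seq_len(k)]) / sum(srt)
  list(share_top = share_top, share_rest = 1 - share_top,
       n_top = k, cutoff_bp = srt[k])
}

#' Chromosome X share of coverage within the longest tracts
#'
#' Pools autosomal and chromosome X tract lengths (from matched samples of the
#' two inheritance modes), takes the `ceiling(top_fraction * n)` longest
#' tracts of the pool, and reports chromosome X's share of the base pairs in
#' that top set and in the remainder. When the longest tracts are
#' preferentially X-linked, `x_share_top` exceeds both 0.5 and `x_share_rest`.
#'
#' @param aut_lengths,x_lengths tract lengths in bp (or two-column tract
#'   matrices) from autosomal and chrX samples of equal size.
#' @param top_fraction fraction of pooled tracts counted as "longest".
#' @return List with `x_share_top`, `x_share_rest`, `n_top`, `cutoff_bp`.
#' @export
longest_tract_composition <- function(aut_lengths, x_lengths,
                                      top_fraction = 0.01) {
  aut <- tract_lengths(aut_lengths)
  x <- tract_lengths(x_lengths)
  if (length(aut) == 0 || length(x) == 0) {
    stop("domain error: empty tract set")
  }
  if (top_fraction <= 0 || top_fraction >= 1) {
    stop("domain error: top_fraction must be in (0, 1)")
  }
  lens <- c(aut, x)
  is_x <- rep(c(FALSE, TRUE), c(length(aut), length(x)))
  ord <- order(lens, decreasing = TRUE)
  k <- ceiling(top_fraction * length(lens))
  top <- ord[seq_len(k)]
  rest <- ord[-seq_len(k)]
  list(
    x_share_top = sum(lens[top][is_x[top]]) / sum(lens[top]),
    x_share_rest = sum(lens[rest][is_x[rest]]) / sum(lens[rest]),
    n_top = k, cutoff_bp = lens[ord[k]]
  )
}

#' Nearest-rank tract-length percentile
#'
#' Empirical quantile by the nearest-rank rule: the `ceiling(q * n)`-th
#' smallest length, so results on integer inputs are integer-exact.
#'
#' @param lengths tract lengths in bp, or a two-column tract matrix.
#' @param q quantile in `(0, 1)`, default 0.95.
#' @return The nearest-rank quantile in bp.
#' @export
length_percentile <- function(lengths, q = 0.95) {
  lengths <- tract_lengths(lengths)
  if (length(lengths) == 0) stop("domain error: empty tract set")
  if (q <= 0 || q >= 1) stop("domain error: q must be in (0, 1)")
  sort(lengths)[ceiling(q * length(lengths))]
}
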