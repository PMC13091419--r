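#' Cross- or auto-correlogram of two spike trains
#'
#' Histogram of all pairwise time differences `t_b - t_a` within
#' `[-max_lag, +max_lag]`, in half-open bins of width `bin_ms`.  With
#' `b = a` (the same object) the autocorrelogram is returned with
#' self-pairs removed.
#'
#' @param a,b [spike_train] objects recorded over overlapping intervals.
#' @param bin_ms Bin width, ms.
#' @param max_lag_ms Maximum absolute lag, ms.
#' @return A `correlogram`: data frame with `lag_ms` (bin centres) and
#'   `count`, plus attributes `bin_ms` and `max_lag_ms`.
#' @export
correlogram <- function(a, b = a, bin_ms = 5, max_lag_ms = 100) {
  stopifnot(inherits(a, "spike_train"), inherits(b, "spike_train"))
  auto <- identical(a$times, b$times)
  max_lag <- max_lag_ms / 1000
  bw <- bin_ms / 1000
  n_bins <- 2L * ceiling(max_lag / bw - 1e-9)
  edges <- seq(-n_bins / 2 * bw, n_bins / 2 * bw, by = bw)
  counts <- integer(n_bins)
  ta <- a$times
  tb <- b$times
  if (length(ta) && length(tb)) {
    lo <- 1L
    hi <- 0L
    for (i in seq_along(ta)) {
      while (lo <= length(tb) && tb[lo] < ta[i] - max_lag) lo <- lo + 1L
      if (hi < lo - 1L) hi <- lo - 1L
      while (hi < length(tb) && tb[hi + 1L] <= ta[i] + max_lag) hi <- hi + 1L
      if (hi >= lo) {
        d <- tb[lo:hi] - ta[i]
        if (auto) d <- d[lo:hi != i]
        # half-open [lo, hi); the epsilon keeps edge lags in the upper
        # bin despite floating-point rounding
        idx <- floor((d - edges[1L]) / bw + 1e-9) + 1L
        idx <- idx[idx >= 1L & idx <= n_bins]
        counts <- counts + tabulate(idx, nbins = n_bins)
      }
    }
  }
  structure(data.frame(lag_ms = (edges[-1L] + edges[-length(edges)]) / 2 * 1000,
                       count = counts),
            class = c("correlogram", "data.frame"),
            bin_ms = bin_ms, max_lag_ms = max_lag_ms)
}

#' Binned instantaneous firing rate
#'
#' Bins a spike train into counts per `bin_ms` (half-open bins), divides
#' by the bin width to obtain Hz, and optionally convolves with a
#' Gaussian kernel.  The total spike count is preserved before
#' smoothing.
#'
#' @param train A [spike_train].
#' @param bin_ms Bin width in ms (protocol value 12.5).
#' @param smooth_sigma_ms Gaussian kernel sd in ms; `0` leaves the
#'   series untouched.
#' @return Numeric rate series (Hz), with attribute `bin_ms`.
#' @export
binned_rate <- function(train, bin_ms = 12.5, smooth_sigma_ms = 25) {
  stopifnot(inherits(train, "spike_train"), bin_ms > 0)
  bw <- bin_ms / 1000
  n_bins <- max(1L, ceiling(train$duration / bw - 1e-9))
  idx <- pmin(n_bins, floor(train$times / bw) + 1L)
  counts <- tabulate(idx, nbins = n_bins)
  rate <- counts / bw
  if (smooth_sigma_ms > 0) {
    sigma <- smooth_sigma_ms / bin_ms
    half <- ceiling(4 * sigma)
    k <- stats::dnorm(seq(-half, half), sd = sigma)
    k <- k / sum(k)
    padded <- c(rep(rate[1L], half), rate, rep(rate[n_bins], half))
    sm <- stats::filter(padded, k, sides = 2)
    rate <- as.numeric(sm)[(half + 1L):(half + n_bins)]
  }
  structure(rate, bin_ms = bin_ms)
}

#' Spike-spike coherence of two trains
#'
#' Bins both trains into counts at `bin_rate_hz`, mean-subtracts, and
#' estimates the Welch magnitude-squared coherence (Hann taper,
#' `nfft`-sample blocks, 5% overlap).  The scalar summary is the mean
#' coherence over `summary_range` (0.5-100 Hz).
#'
#' @param a,b [spike_train] objects over the same interval.
#' @param bin_rate_hz Binning rate for the count series (default 1000).
#' @param nfft,overlap Welch parameters.
#' @param summary_range Two-element Hz range for the scalar summary.
#' @return List: `freq`, `coherence` (in `[0,1]`), `mean_coherence`,
#'   `n_segments`.
#' @export
spike_spike_coherence <- function(a, b, bin_rate_hz = 1000, nfft = 256,
                                  overlap = 0.05,
                                  summary_range = c(0.5, 100)) {
  stopifnot(inherits(a, "spike_train"), inherits(b, "spike_train"))
  dur <- min(a$duration, b$duration)
  bw <- 1 / bin_rate_hz
  n <- floor(dur / bw)
  if (n < nfft) {
    stop("recording shorter than one spectral block", call. = FALSE)
  }
  bin_counts <- function(tr) {
    idx <- floor(tr$times / bw) + 1L
    idx <- idx[idx <= n]
    tabulate(idx, nbins = n)
  }
  xa <- bin_counts(a); xa <- xa - mean(xa)
  xb <- bin_counts(b); xb <- xb - mean(xb)
  ch <- welch_coherence(xa, xb, fs = bin_rate_hz, nfft = nfft,
                        overlap = overlap)
  sel <- ch$freq >= summary_range[1L] & ch$freq <= summary_range[2L]
  c(ch, list(mean_coherence = mean(ch$coherence[sel])))
}

#' Pairwise squared-correlation matrix of unit rate series
#'
#' Entry (i, j) is the squared linear correlation coefficient of the two
#' smoothed rate series over the analysis window (e.g. rotarod start to
#' fall-off).
#'
#' @param rates Named list of equal-length rate series (from
#'   [binned_rate]).
#' @param window Optional two-element time window in seconds (requires
#'   the series' `bin_ms` attribute); default uses the whole series.
#' @return A `crosscorr_matrix`: symmetric numeric matrix of R-squared
#'   values in `[0,1]` with unit diagonal, dimnames = unit ids.
#'   Zero-variance series produce 0 entries with a warning.
#' @export
pairwise_r2_matrix <- function(rates, window = NULL) {
  if (length(rates) < 2L) stop("need at least 2 units", call. = FALSE)
  lens <- vapply(rates, length, 0L)
  if (length(unique(lens)) != 1L) {
    stop("rate series must be aligned to equal length", call. = FALSE)
  }
  if (!is.null(window)) {
    bw <- attr(rates[[1L]], "bin_ms") / 1000
    i0 <- max(1L, floor(window[1L] / bw) + 1L)
    i1 <- min(lens[1L], ceiling(window[2L] / bw))
    rates <- lapply(rates, function(x) x[i0:i1])
  }
  X <- do.call(cbind, lapply(rates, as.numeric))
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance rate series; corresponding entries set to 0",
            call. = FALSE)
  }
  R <- suppressWarnings(stats::cor(X))
  R[!is.finite(R)] <- 0
  M <- R^2
  diag(M) <- 1
  dimnames(M) <- list(names(rates), names(rates))
  class(M) <- c("crosscorr_matrix", class(M))
  M
}

#' Hierarchical-clustering leaf order of a correlation matrix
#'
#' Agglomerative clustering (average linkage) on distance `1 - R2`; the
#' dendrogram leaf order gives the unit ordering used to display the
#' matrices.  When every off-diagonal distance is identical (no
#' structure) the input order is returned.
#'
#' @param m A matrix from [pairwise_r2_matrix].
#' @return Character vector of unit ids in leaf order.
#' @export
cluster_order <- function(m) {
  ids <- rownames(m)
  d <- 1 - m[upper.tri(m)]
  if (length(unique(round(d, 12))) <= 1L) return(ids)
  hc <- stats::hclust(stats::as.dist(1 - m), method = "average")
  ids[hc$order]
}

#' Similarity of two correlation matrices
#'
#' Linear correlation of the vectorized strict upper triangles; the
#' measure used to compare session matrices across training days.
#'
#' @param m1,m2 Matrices over the same unit set and order.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
matrix_similarity <- function(m1, m2) {
  if (!identical(dim(m1), dim(m2)) ||
      !identical(rownames(m1), rownames(m2))) {
    stop("matrices must share the same unit set and order", call. = FALSE)
  }
  stats::cor(m1[upper.tri(m1)], m2[upper.tri(m2)])
}
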