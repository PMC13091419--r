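new_waveform_set <- function(waves, fs, align_sample = 10L) {
  stopifnot(length(dim(waves)) == 3L)
  structure(list(waves = waves, fs = fs,
                 align_sample = as.integer(align_sample),
                 n_events = dim(waves)[1L],
                 n_channels = dim(waves)[2L],
                 n_samples = dim(waves)[3L]),
            class = "waveform_set")
}

#' @export
print.waveform_set <- function(x, ...) {
  cat(sprintf("<waveform_set> %d events x %d channels x %d samples at %g Hz\n",
              x$n_events, x$n_channels, x$n_samples, x$fs))
  invisible(x)
}

#' Zero-phase spike-band filter
#'
#' Band-passes a wideband trace into the 600-6000 Hz spike band with a
#' zero-phase (forward-backward) Butterworth filter; length preserved.
#'
#' @param raw Numeric wideband trace, microvolts.
#' @param fs Sampling rate; must exceed 12 kHz (twice the upper edge).
#' @param band Filter edges in Hz.
#' @return Filtered trace of the same length.
#' @export
bandpass_spike_filter <- function(raw, fs, band = c(600, 6000)) {
  if (fs <= 2 * band[2L]) {
    stop(sprintf("fs = %g Hz too low for a %g Hz band edge", fs, band[2L]),
         call. = FALSE)
  }
  bandpass_filter(raw, fs, band[1L], band[2L], order = 2L)
}

#' Detect spikes by negative threshold crossing
#'
#' Finds negative-going crossings of `-threshold_uv` (extracellular
#' trough-first convention) with a refractory lockout of one window, and
#' cuts a `window`-sample waveform around each crossing with the
#' crossing placed at the alignment sample.
#'
#' @param filtered Spike-band filtered trace (one channel), microvolts.
#' @param fs Sampling rate, Hz.
#' @param threshold_uv Detection threshold (positive number; the trace
#'   must drop below its negative), typically 50.
#' @param window Samples per cut waveform (default 40).
#' @param align_sample Sample index of the crossing within the window
#'   (default 10).
#' @return A `waveform_set` (events x 1 channel x window); empty when no
#'   crossing occurs.
#' @export
detect_spikes <- function(filtered, fs, threshold_uv = 50, window = 40L,
                          align_sample = 10L) {
  n <- length(filtered)
  if (n <= window) stop("trace shorter than one window", call. = FALSE)
  below <- filtered < -threshold_uv
  crossings <- which(below & !c(FALSE, below[-n]))
  keep <- integer()
  last <- -Inf
  for (i in crossings) {
    if (i - last >= window) {       # refractory lockout of one window
      keep <- c(keep, i)
      last <- i
    }
  }
  pre <- align_sample - 1L
  post <- window - align_sample
  keep <- keep[keep - pre >= 1L & keep + post <= n]
  waves <- array(0, dim = c(length(keep), 1L, window))
  for (k in seq_along(keep)) {
    waves[k, 1L, ] <- filtered[(keep[k] - pre):(keep[k] + post)]
  }
  ws <- new_waveform_set(waves, fs = fs, align_sample = align_sample)
  ws$crossing_index <- keep
  ws
}

#' Average waveform of a set
#'
#' @param ws A `waveform_set` with at least one event.
#' @return Channels x samples matrix of arithmetic means.
#' @export
average_waveform <- function(ws) {
  stopifnot(inherits(ws, "waveform_set"))
  if (ws$n_events < 1L) stop("cannot average an empty waveform set",
                             call. = FALSE)
  apply(ws$waves, c(2L, 3L), mean)
}

#' Waveform features of a unit
#'
#' Computes the classification features from a mean waveform: the
#' trough-to-peak time (global trough to the subsequent global peak,
#' ties toward the earlier sample), the trough width at half amplitude
#' (linear interpolation between samples), the peak-to-trough amplitude,
#' and the mean firing rate from the unit's spike train.
#'
#' @param mean_wf Channels x samples matrix (or a vector for one
#'   channel); the channel with the deepest trough is used.
#' @param fs Sampling rate, Hz.
#' @param train Optional [spike_train] supplying the mean rate.
#' @return List of class `unit_features`: `trough_to_peak_ms`,
#'   `half_width_ms`, `peak_amplitude_uv`, `mean_rate_hz`.
#' @export
waveform_features <- function(mean_wf, fs, train = NULL) {
  if (is.null(dim(mean_wf))) mean_wf <- matrix(mean_wf, nrow = 1L)
  ch <- which.min(apply(mean_wf, 1L, min))
  w <- mean_wf[ch, ]
  n <- length(w)
  trough <- which.min(w)
  if (trough == n || min(w) >= 0) {
    stop("waveform has no usable trough", call. = FALSE)
  }
  after <- w[(trough + 1L):n]
  peak <- trough + which.max(after)        # which.max ties -> earlier
  ttp_ms <- (peak - trough) / fs * 1000
  half <- w[trough] / 2                    # half of (negative) trough
  # crossings of the half level on each side of the trough
  left <- trough
  while (left > 1L && w[left] <= half) left <- left - 1L
  right <- trough
  while (right < n && w[right] <= half) right <- right + 1L
  interp <- function(i0, i1) {
    if (w[i1] == w[i0]) return(i0)
    i0 + (half - w[i0]) / (w[i1] - w[i0])
  }
  x_left <- if (w[left] > half) interp(left, left + 1L) else left
  x_right <- if (w[right] > half) interp(right - 1L, right) else right
  hw_ms <- (x_right - x_left) / fs * 1000
  structure(list(
    trough_to_peak_ms = ttp_ms,
    half_width_ms = hw_ms,
    peak_amplitude_uv = w[peak] - w[trough],
    mean_rate_hz = if (is.null(train)) NA_real_ else mean_rate(train)),
    class = "unit_features")
}

#' Principal-component projection of a waveform set
#'
#' Visualization helper in the style of sorter "energy plots": projects
#' per-event concatenated waveforms onto principal components ordered by
#' variance, with each component's sign fixed so its largest-magnitude
#' loading is positive.
#'
#' @param ws A `waveform_set`.
#' @param n_components Number of components to return.
#' @return Events x components score matrix.
#' @export
waveform_pca <- function(ws, n_components = 2L) {
  stopifnot(inherits(ws, "waveform_set"))
  X <- matrix(ws$waves, nrow = ws$n_events)
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$rotation))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  scale(X, center = p$center, scale = FALSE) %*% rot
}
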