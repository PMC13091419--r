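#' Welch power spectrum of an LFP signal
#'
#' Segment-averaged one-sided power spectral density (Hann taper,
#' `nfft`-point blocks, 5% overlap).  The density integrates to the
#' signal variance (Parseval consistency within a few percent).
#'
#' @param lfp An [lfp_signal] of at least `nfft` samples.
#' @param nfft Block length (protocol value 256).
#' @param overlap Overlap fraction between consecutive blocks (0.05).
#' @return A `power_spectrum`: data frame with `freq_hz` (uniform grid
#'   from 0 to Nyquist) and `power` (uV^2/Hz), plus attributes `nfft`,
#'   `overlap`, `fs`, `n_segments`.
#' @export
power_spectrum <- function(lfp, nfft = 256, overlap = 0.05) {
  stopifnot(inherits(lfp, "lfp_signal"))
  sp <- welch_spectra(lfp$samples, fs = lfp$fs, nfft = nfft,
                      overlap = overlap)
  structure(data.frame(freq_hz = sp$freq, power = sp$Sxx),
            class = c("power_spectrum", "data.frame"),
            nfft = nfft, overlap = overlap, fs = lfp$fs,
            n_segments = sp$n_segments)
}

#' Area under the power spectrum per oscillation band
#'
#' Trapezoidal integral of the spectral density over each band (delta
#' 0-4, theta 4-8, alpha 8-12, beta 12-30, gamma 30-50 Hz by default).
#'
#' @param ps A `power_spectrum`.
#' @param bands Named list of two-element Hz ranges; all edges must lie
#'   within the spectrum's frequency range.
#' @return Named numeric vector of non-negative band areas (uV^2).
#' @export
band_auc <- function(ps, bands = analysis_config()$bands) {
  f <- ps$freq_hz
  p <- ps$power
  vapply(bands, function(b) trapz_band(f, p, b[1L], b[2L]), 0)
}

#' Decimate an LFP signal to a lower analysis rate
#'
#' Anti-alias low-pass (zero-phase Butterworth at 80% of the target
#' Nyquist) followed by integer subsampling.
#'
#' @param lfp An [lfp_signal].
#' @param target_fs Target rate in Hz; must divide `lfp$fs` to an
#'   integer factor.
#' @return The decimated `lfp_signal`.
#' @export
lfp_decimate <- function(lfp, target_fs = 500) {
  stopifnot(inherits(lfp, "lfp_signal"))
  fac <- lfp$fs / target_fs
  if (abs(fac - round(fac)) > 1e-9) {
    stop("target_fs must divide the input rate", call. = FALSE)
  }
  fac <- as.integer(round(fac))
  if (fac == 1L) return(lfp)
  bf <- signal::butter(4, (0.8 * target_fs / 2) / (lfp$fs / 2), type = "low")
  y <- as.numeric(signal::filtfilt(bf, lfp$samples))
  lfp_signal(y[seq(1L, length(y), by = fac)], fs = target_fs,
             region = lfp$region, group = lfp$group)
}

#' Spike-field coherence spectrum
#'
#' Bins the spike train on the LFP sample grid into a 0/1 indicator
#' (multiple spikes in one sample collapse to 1, with a message),
#' mean-subtracts both series, and estimates Welch magnitude-squared
#' coherence between the spike indicator and the LFP; band means are
#' reported for the configured oscillation bands.
#'
#' @param train A non-empty [spike_train] covering the LFP interval.
#' @param lfp An [lfp_signal].
#' @param nfft,overlap Welch parameters.
#' @param bands Named band list for the band means.
#' @return A `coherence_spectrum`: list with `freq`, `coherence` (in
#'   `[0,1]`), `band_means` (named), `n_segments`.
#' @export
spike_field_coherence <- function(train, lfp, nfft = 256, overlap = 0.05,
                                  bands = analysis_config()$bands) {
  stopifnot(inherits(train, "spike_train"), inherits(lfp, "lfp_signal"))
  if (length(train$times) == 0L) {
    stop("empty spike train: coherence undefined", call. = FALSE)
  }
  if (train$duration > lfp$duration + 1 / lfp$fs) {
    stop("spike train extends beyond the LFP interval", call. = FALSE)
  }
  n <- length(lfp$samples)
  idx <- pmin(n, floor(train$times * lfp$fs) + 1L)
  collapsed <- length(idx) - length(unique(idx))
  if (collapsed > 0L) {
    message(sprintf("%d spike(s) collapsed onto occupied LFP samples",
                    collapsed))
  }
  s <- numeric(n)
  s[unique(idx)] <- 1
  s <- s - mean(s)
  x <- lfp$samples - mean(lfp$samples)
  ch <- welch_coherence(s, x, fs = lfp$fs, nfft = nfft, overlap = overlap)
  band_means <- vapply(bands, function(b) {
    sel <- ch$freq >= b[1L] & ch$freq <= b[2L]
    mean(ch$coherence[sel])
  }, 0)
  structure(list(freq = ch$freq, coherence = ch$coherence,
                 band_means = band_means, n_segments = ch$n_segments),
            class = "coherence_spectrum")
}
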