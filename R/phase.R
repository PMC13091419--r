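#' Band-limited phase and amplitude envelope of an LFP
#'
#' Zero-phase band-pass into the requested band (default the 4-12 Hz
#' theta-alpha coupling band) followed by the analytic-signal
#' construction.  Phase follows the cosine convention: 0 at the
#' oscillation peak, pi at the trough; returned wrapped to `[0, 2*pi)`.
#'
#' @param lfp An [lfp_signal].
#' @param band Two-element Hz range below Nyquist.
#' @return List: `phase` (radians per sample), `envelope` (uV), `fs`.
#' @export
band_phase <- function(lfp, band = c(4, 12)) {
  stopifnot(inherits(lfp, "lfp_signal"))
  if (max(band) >= lfp$fs / 2) stop("band outside Nyquist", call. = FALSE)
  if (stats::sd(lfp$samples) == 0) {
    stop("constant signal: phase undefined (zero envelope)", call. = FALSE)
  }
  y <- bandpass_filter(lfp$samples, lfp$fs, band[1L], band[2L])
  z <- analytic_signal(y)
  list(phase = Arg(z) %% (2 * pi), envelope = Mod(z), fs = lfp$fs)
}

#' Phase of each spike
#'
#' Assigns each spike the band phase at the nearest LFP sample.
#'
#' @param train A [spike_train] whose spikes lie within the LFP
#'   interval.
#' @param phase Phase series from [band_phase] (or a numeric vector).
#' @param fs Sampling rate of the phase series (taken from a
#'   [band_phase] result automatically).
#' @return Numeric vector of angles in `[0, 2*pi)`, one per spike.
#' @export
spike_phases <- function(train, phase, fs = NULL) {
  stopifnot(inherits(train, "spike_train"))
  if (is.list(phase)) {
    fs <- phase$fs
    phase <- phase$phase
  }
  if (is.null(fs)) stop("`fs` required for a bare phase vector", call. = FALSE)
  if (length(train$times) == 0L) return(numeric())
  n <- length(phase)
  idx <- round(train$times * fs) + 1L
  # a spike at the recording end rounds one past the grid; it is still
  # inside the interval, so clamp to the last sample
  bad <- which(idx < 1L | train$times * fs > n + 0.5)
  if (length(bad)) {
    stop(sprintf("spike(s) outside the LFP interval at indices: %s",
                 paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  }
  phase[pmin(idx, n)]
}

#' Phase-locking value and mean resultant angle
#'
#' `PLV = |mean of unit phasors|` in `[0, 1]`; the mean angle is the
#' argument of the resultant vector.
#'
#' @param angles Non-empty numeric vector of angles, radians.
#' @return List: `plv`, `mean_angle` (radians in `[0, 2*pi)`).
#' @export
plv <- function(angles) {
  if (length(angles) == 0L) stop("empty angle sample", call. = FALSE)
  z <- mean(exp(1i * angles))
  list(plv = Mod(z), mean_angle = Arg(z) %% (2 * pi))
}

#' Rayleigh test of circular uniformity
#'
#' `Z = n * PLV^2`; the p value uses the standard small-sample
#' correction `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))` with
#' `R = n * PLV`, clipped to `[0, 1]`.
#'
#' @param angles Numeric vector of angles, radians.  Fewer than 10
#'   angles triggers a warning (approximation degrades) but the p value
#'   is still returned.
#' @return List: `Z`, `p`, `n`, `plv`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n == 0L) stop("empty angle sample", call. = FALSE)
  if (n < 10L) warning("Rayleigh approximation unreliable for n < 10",
                       call. = FALSE)
  v <- plv(angles)
  R <- n * v$plv
  Z <- R^2 / n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(Z = Z, p = min(1, max(0, p)), n = n, plv = v$plv)
}

#' Phase histogram
#'
#' Counts over `[0, 2*pi)` in `n_bins` equal half-open bins; suitable
#' for both polar and linear display.  Counts always sum to the number
#' of angles.
#'
#' @param angles Numeric vector of angles, radians (wrapped
#'   internally).
#' @param n_bins Number of bins (>= 4).
#' @return Data frame: `bin_centre_rad`, `bin_centre_deg`, `count`.
#' @export
phase_histogram <- function(angles, n_bins = 18L) {
  if (n_bins < 4L) stop("need at least 4 bins", call. = FALSE)
  a <- angles %% (2 * pi)
  idx <- pmin(n_bins, floor(a / (2 * pi / n_bins)) + 1L)
  counts <- tabulate(idx, nbins = n_bins)
  centres <- (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  data.frame(bin_centre_rad = centres,
             bin_centre_deg = centres * 180 / pi,
             count = counts)
}

#' Phase-amplitude modulation index
#'
#' Entropy-based coupling measure: the amplitude envelope is averaged
#' within each of `n_bins` phase bins, normalised to a distribution
#' `p_j`, and `MI = (ln N - H(p)) / ln N` with `H` the Shannon entropy.
#' `MI = 0` for a phase-independent envelope, `MI = 1` when all
#' envelope mass falls in a single bin.
#'
#' @param phase Phase series, radians (wrapped internally).
#' @param envelope Amplitude envelope aligned with `phase`; must not be
#'   all zero.
#' @param n_bins Number of phase bins (conventional default 18).
#' @return MI in `[0, 1]`.
#' @export
modulation_index <- function(phase, envelope, n_bins = 18L) {
  if (length(phase) != length(envelope)) {
    stop("phase and envelope must be aligned", call. = FALSE)
  }
  if (all(envelope == 0)) stop("all-zero envelope", call. = FALSE)
  if (any(envelope < 0)) stop("envelope must be non-negative", call. = FALSE)
  idx <- pmin(n_bins, floor((phase %% (2 * pi)) / (2 * pi / n_bins)) + 1L)
  m <- vapply(seq_len(n_bins), function(j) {
    e <- envelope[idx == j]
    if (length(e)) mean(e) else 0
  }, 0)
  p <- m / sum(m)
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  (log(n_bins) - h) / log(n_bins)
}

# Entropy-normalised concentration of a binned distribution:
# (ln N - H(p)) / ln N, the same normalisation the modulation index
# applies to the envelope-by-phase distribution.
entropy_concentration <- function(p) {
  p <- p / sum(p)
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  (log(length(p)) - h) / log(length(p))
}

#' Full spike-phase statistics of one unit
#'
#' Convenience wrapper combining [band_phase], [spike_phases], [plv],
#' [rayleigh_test] and [modulation_index] for a unit and its
#' simultaneously recorded LFP.
#'
#' @param train A [spike_train].
#' @param lfp An [lfp_signal].
#' @param band Coupling band, Hz.
#' @param n_bins Phase bins for the modulation index.
#' @return List of class `phase_stats`: `n`, `plv`, `mean_angle_rad`,
#'   `mean_angle_deg`, `rayleigh_z`, `rayleigh_p`, `mi` (the
#'   entropy-normalised concentration of the spike-phase histogram --
#'   the same `(ln N - H)/ln N` construction as [modulation_index],
#'   applied to the spike density over phase bins, quantifying
#'   phase-locking bias in `[0, 1]`).
#' @export
phase_stats <- function(train, lfp, band = c(4, 12), n_bins = 18L) {
  bp <- band_phase(lfp, band = band)
  ang <- spike_phases(train, bp)
  if (length(ang) == 0L) stop("empty spike train", call. = FALSE)
  v <- plv(ang)
  rt <- rayleigh_test(ang)
  hist_counts <- phase_histogram(ang, n_bins = n_bins)$count
  structure(list(n = length(ang), plv = v$plv,
                 mean_angle_rad = v$mean_angle,
                 mean_angle_deg = v$mean_angle * 180 / pi,
                 rayleigh_z = rt$Z, rayleigh_p = rt$p,
                 mi = entropy_concentration(hist_counts)),
            class = "phase_stats")
}
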