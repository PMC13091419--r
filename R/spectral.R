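# Welch segment-averaged spectral estimates and the analytic signal.
# Shared by the power-spectrum, coherence and phase modules.

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

# Segment-averaged auto/cross spectra with a Hann taper.
# overlap is the fraction of nfft shared by consecutive segments.
# Returns one-sided grids: freq (0..Nyquist), Sxx, Syy (real), Sxy (complex).
welch_spectra <- function(x, y = NULL, fs, nfft = 256, overlap = 0.05,
                          demean_segments = TRUE) {
  n <- length(x)
  if (!is.null(y) && length(y) != n) {
    stop("signals must have equal length", call. = FALSE)
  }
  if (n < nfft) {
    stop(sprintf("signal (%d samples) shorter than one %d-sample block",
                 n, nfft), call. = FALSE)
  }
  step <- max(1L, as.integer(round(nfft * (1 - overlap))))
  starts <- seq.int(1L, n - nfft + 1L, by = step)
  w <- hann_window(nfft)
  u <- sum(w^2)                       # window power normalisation
  nf <- nfft %/% 2L + 1L
  Sxx <- numeric(nf)
  Syy <- numeric(nf)
  Sxy <- complex(nf)
  for (s in starts) {
    xs <- x[s:(s + nfft - 1L)]
    if (demean_segments) xs <- xs - mean(xs)
    X <- stats::fft(xs * w)[1:nf]
    Sxx <- Sxx + Re(X * Conj(X))
    if (!is.null(y)) {
      ys <- y[s:(s + nfft - 1L)]
      if (demean_segments) ys <- ys - mean(ys)
      Y <- stats::fft(ys * w)[1:nf]
      Syy <- Syy + Re(Y * Conj(Y))
      Sxy <- Sxy + X * Conj(Y)
    }
  }
  k <- length(starts)
  scale <- 1 / (k * fs * u)
  # one-sided: double all bins except DC and (for even nfft) Nyquist
  dbl <- rep(2, nf)
  dbl[1L] <- 1
  if (nfft %% 2L == 0L) dbl[nf] <- 1
  list(freq = (0:(nf - 1L)) * fs / nfft,
       Sxx = Sxx * scale * dbl,
       Syy = if (is.null(y)) NULL else Syy * scale * dbl,
       Sxy = if (is.null(y)) NULL else Sxy * scale * dbl,
       n_segments = k)
}

# Magnitude-squared coherence from Welch spectra; in [0,1] by
# Cauchy-Schwarz once >1 segment is averaged.
welch_coherence <- function(x, y, fs, nfft = 256, overlap = 0.05) {
  sp <- welch_spectra(x, y, fs = fs, nfft = nfft, overlap = overlap)
  denom <- sp$Sxx * sp$Syy
  coh <- ifelse(denom > 0, Mod(sp$Sxy)^2 / denom, 0)
  list(freq = sp$freq, coherence = pmin(1, coh), n_segments = sp$n_segments)
}

# Analytic signal via the frequency-domain construction: zero the
# negative frequencies, double the positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Trapezoidal integral of y(x) over [a, b] with linear interpolation at
# the end points; x must be increasing.
trapz_band <- function(x, y, a, b) {
  if (a < x[1L] || b > x[length(x)]) {
    stop(sprintf("band [%g, %g] outside spectrum range [%g, %g]",
                 a, b, x[1L], x[length(x)]), call. = FALSE)
  }
  inside <- x > a & x < b
  xs <- c(a, x[inside], b)
  ys <- c(stats::approx(x, y, a)$y, y[inside], stats::approx(x, y, b)$y)
  sum(diff(xs) * (ys[-1L] + ys[-length(ys)])) / 2
}

# Zero-phase Butterworth band-pass (order 4 applied forward+backward).
bandpass_filter <- function(x, fs, lo, hi, order = 4L) {
  nyq <- fs / 2
  if (hi >= nyq) {
    stop(sprintf("band edge %g Hz at or above Nyquist (%g Hz)", hi, nyq),
         call. = FALSE)
  }
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}
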