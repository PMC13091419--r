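# Longitudinal unit-identity tracking across the 7-day rotarod
# protocol: waveform similarity, amplitude drift, firing-statistics
# divergence, percentile-calibrated stability, and the reactive /
# non-reactive / HI-affected learning-response classification.

#' Maximum time-shifted waveform correlation
#'
#' Similarity of two averaged spike waveforms as the maximum over
#' integer shifts of their linear correlation, with the Fisher
#' z-transform (`atanh`, r clipped to +/-0.9999) for downstream
#' normality.
#'
#' @param w_day1,w_dayk Equal-length numeric waveforms (use the peak
#'   channel of the averaged waveform).
#' @param max_shift_samples Maximum |shift|; must be below half the
#'   waveform length.
#' @return List: `max_r`, `fisher_z`, `best_shift`.
#' @export
waveform_similarity <- function(w_day1, w_dayk, max_shift_samples = 5L) {
  n <- length(w_day1)
  if (length(w_dayk) != n) stop("waveforms must have equal length",
                                call. = FALSE)
  if (max_shift_samples >= n / 2) stop("max shift too large", call. = FALSE)
  if (stats::sd(w_day1) == 0 || stats::sd(w_dayk) == 0) {
    stop("zero-variance waveform", call. = FALSE)
  }
  best <- -Inf
  best_shift <- 0L
  for (s in seq.int(-max_shift_samples, max_shift_samples)) {
    if (s >= 0) {
      a <- w_day1[1:(n - s)]
      b <- w_dayk[(1 + s):n]
    } else {
      a <- w_day1[(1 - s):n]
      b <- w_dayk[1:(n + s)]
    }
    r <- suppressWarnings(stats::cor(a, b))
    if (is.finite(r) && r > best) {
      best <- r
      best_shift <- s
    }
  }
  r_clip <- max(-0.9999, min(0.9999, best))
  list(max_r = best, fisher_z = atanh(r_clip), best_shift = best_shift)
}

#' Normalised trough-to-peak amplitude change
#'
#' Ratio of the spike-amplitude change on a given day relative to
#' day 1: `|A_k - A_1| / A_1`, with `A` the trough-to-peak amplitude of
#' the averaged waveform.
#'
#' @param w_day1,w_dayk Numeric waveforms (peak channel).
#' @return Non-negative dimensionless ratio.
#' @export
amplitude_change <- function(w_day1, w_dayk) {
  amp <- function(w) max(w) - min(w)
  a1 <- amp(w_day1)
  ak <- amp(w_dayk)
  if (a1 <= 0) stop("day-1 amplitude is zero", call. = FALSE)
  abs(ak - a1) / a1
}

#' Log-scaled firing-statistics histograms of a unit
#'
#' The two normalised densities used for identity tracking: an
#' interspike-interval histogram over 100 log-spaced bins from 0.5 to
#' 1e5 ms, and an autocorrelogram over +/-100 ms in 100 bins.  Both are
#' smoothed additively with `eps = 1e-6` before normalising to sum 1.
#'
#' @param train A [spike_train] with at least 2 spikes.
#' @param eps Additive smoothing constant.
#' @return List: `isih`, `acorr` (numeric densities summing to 1),
#'   `isih_breaks_ms`, `acorr_breaks_ms`.
#' @export
log_histograms <- function(train, eps = 1e-6) {
  stopifnot(inherits(train, "spike_train"))
  if (length(train$times) < 2L) stop("need at least 2 spikes", call. = FALSE)
  isi_ms <- diff(train$times) * 1000
  breaks <- 10^seq(log10(0.5), 5, length.out = 101L)
  isi_ms <- pmin(pmax(isi_ms, 0.5), 1e5)
  counts <- graphics::hist(isi_ms, breaks = breaks, plot = FALSE)$counts
  isih <- counts + eps
  isih <- isih / sum(isih)
  cg <- correlogram(train, bin_ms = 2, max_lag_ms = 100)
  acorr <- cg$count + eps
  acorr <- acorr / sum(acorr)
  list(isih = isih, acorr = acorr,
       isih_breaks_ms = breaks,
       acorr_breaks_ms = seq(-100, 100, by = 2))
}

#' Kullback-Leibler divergence of two binned densities
#'
#' `KL(p || q) = sum p * ln(p / q) >= 0`, with equality iff `p = q`.
#' The reported tracking statistic is `ln(KL + eps)` (the log transform
#' brings the within-day distribution toward normality); the raw value
#' is returned alongside.
#'
#' @param p,q Equal-length non-negative vectors, already smoothed and
#'   normalised (see [log_histograms]).
#' @param eps Offset inside the log transform.
#' @return List: `kl`, `log_kl`.
#' @export
kl_divergence <- function(p, q, eps = 1e-6) {
  if (length(p) != length(q)) stop("binning mismatch", call. = FALSE)
  if (any(p < 0) || any(q < 0)) stop("densities must be >= 0", call. = FALSE)
  sel <- p > 0
  kl <- sum(p[sel] * log(p[sel] / q[sel]))
  list(kl = kl, log_kl = log(kl + eps))
}

#' Tracking scores between two days of one unit
#'
#' Convenience wrapper computing the four stability measures between a
#' reference day and a later day: `max_r`/`fisher_z` (waveform shape),
#' `delta_p_amp` (amplitude drift), and `kl_isih`/`kl_acorr`
#' (log-transformed firing-statistics divergences).
#'
#' @param w1,w2 Peak-channel averaged waveforms of the two days.
#' @param train1,train2 [spike_train]s of the two days.
#' @param max_shift_samples Shift range for [waveform_similarity].
#' @return List of class `tracking_score` with fields `max_r`,
#'   `fisher_z`, `delta_p_amp`, `kl_isih`, `kl_acorr`.
#' @export
tracking_score <- function(w1, w2, train1, train2, max_shift_samples = 5L) {
  ws <- waveform_similarity(w1, w2, max_shift_samples)
  h1 <- log_histograms(train1)
  h2 <- log_histograms(train2)
  structure(list(max_r = ws$max_r, fisher_z = ws$fisher_z,
                 delta_p_amp = amplitude_change(w1, w2),
                 kl_isih = kl_divergence(h1$isih, h2$isih)$log_kl,
                 kl_acorr = kl_divergence(h1$acorr, h2$acorr)$log_kl),
            class = "tracking_score")
}

#' Stability decision for day-pair tracking scores
#'
#' Thresholds are calibrated from within-day split-half scores of the
#' same units, which are assumed stable: the 99th percentile of
#' `kl_isih`, `kl_acorr` and `delta_p_amp` and the 1st percentile of
#' `fisher_z`.  A day pair is called stable iff all four measures fall
#' on the stable side (conjunctive rule).  The fraction of calibration
#' pairs failing their own criterion estimates the false-negative rate.
#'
#' @param scores A `tracking_score` (or list of them) for the day
#'   pair(s) under test.
#' @param calibration List of at least 10 `tracking_score`s from
#'   within-day split halves.
#' @return List: `stable` (logical vector), `thresholds`,
#'   `false_negative_rate`.
#' @export
assess_stability <- function(scores, calibration) {
  if (inherits(scores, "tracking_score")) scores <- list(scores)
  if (length(calibration) < 10L) {
    stop("need a calibration set of at least 10 units", call. = FALSE)
  }
  get <- function(lst, f) vapply(lst, function(s) s[[f]], 0)
  thr <- list(
    kl_isih = stats::quantile(get(calibration, "kl_isih"), 0.99,
                              names = FALSE),
    kl_acorr = stats::quantile(get(calibration, "kl_acorr"), 0.99,
                               names = FALSE),
    delta_p_amp = stats::quantile(get(calibration, "delta_p_amp"), 0.99,
                                  names = FALSE),
    fisher_z = stats::quantile(get(calibration, "fisher_z"), 0.01,
                               names = FALSE))
  is_stable <- function(lst) {
    get(lst, "kl_isih") <= thr$kl_isih &
      get(lst, "kl_acorr") <= thr$kl_acorr &
      get(lst, "delta_p_amp") <= thr$delta_p_amp &
      get(lst, "fisher_z") >= thr$fisher_z
  }
  list(stable = is_stable(scores), thresholds = thr,
       false_negative_rate = mean(!is_stable(calibration)))
}

# Deterministic 1-D two-means split: centres initialised at the range
# extremes, iterated to a fixed point; returns the midpoint of the two
# final centres.
two_means_threshold <- function(x) {
  c1 <- min(x)
  c2 <- max(x)
  if (c1 == c2) return(c1)
  for (it in 1:100) {
    assign2 <- abs(x - c2) < abs(x - c1)
    if (!any(assign2) || all(assign2)) break
    n1 <- mean(x[!assign2])
    n2 <- mean(x[assign2])
    if (n1 == c1 && n2 == c2) break
    c1 <- n1
    c2 <- n2
  }
  (c1 + c2) / 2
}

#' Classify learning response of tracked units
#'
#' For each unit, regresses per-session spike-field coherence on
#' session index over task-on sessions, yielding a regression R-squared
#' and a mean coherence.  Units are classified by quadrant: high
#' R-squared (a consistent trend across training) is reactive; low
#' R-squared with low coherence is non-reactive; low R-squared with
#' constant high coherence is the pathological HI-affected profile.
#' Axis thresholds default to a deterministic two-means split of the
#' cohort values (`thresholds = "two_means"`); cohort medians are
#' available via `thresholds = "median"`, or supply
#' `c(r2 = ..., coherence = ...)` directly.
#'
#' @param series A `session_series_set` from
#'   [simulate_learning_series], or its `sessions` data frame (columns
#'   `unit_id`, `session`, `task_on`, `coherence`).
#' @param thresholds `"two_means"`, `"median"`, or a named numeric
#'   vector with elements `r2` and `coherence`.
#' @return Data frame: `unit_id`, `r2`, `mean_coherence`, `label` (one
#'   of `"reactive"`, `"non_reactive"`, `"affected"`), with the
#'   thresholds used as attributes.
#' @export
classify_learning_response <- function(series, thresholds = "two_means") {
  df <- if (inherits(series, "session_series_set")) series$sessions else series
  needed <- c("unit_id", "session", "task_on", "coherence")
  if (!all(needed %in% names(df))) {
    stop("series must carry columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  per_unit <- lapply(split(df, df$unit_id), function(d) {
    d <- d[d$task_on, ]
    if (nrow(d) < 3L) stop("missing sessions for unit ", d$unit_id[1L],
                           call. = FALSE)
    fit <- stats::lm(coherence ~ session, data = d)
    data.frame(unit_id = d$unit_id[1L],
               r2 = summary(fit)$r.squared,
               mean_coherence = mean(d$coherence),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(per_unit, make.row.names = FALSE))
  if (is.character(thresholds)) {
    thr <- switch(match.arg(thresholds, c("two_means", "median")),
      two_means = c(r2 = two_means_threshold(res$r2),
                    coherence = two_means_threshold(res$mean_coherence)),
      median = c(r2 = stats::median(res$r2),
                 coherence = stats::median(res$mean_coherence)))
  } else {
    thr <- thresholds[c("r2", "coherence")]
  }
  high_r2 <- res$r2 >= thr[["r2"]]
  high_coh <- res$mean_coherence >= thr[["coherence"]]
  res$label <- ifelse(high_r2, "reactive",
                      ifelse(high_coh, "affected", "non_reactive"))
  attr(res, "thresholds") <- thr
  res
}
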