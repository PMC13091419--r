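# Synthetic cohort generator.  Emulates the statistical structure the
# in-vivo findings rest on -- four hemisphere groups x two regions, with
# the injured (ipsilateral) hemisphere showing fewer units, reduced
# pyramidal rates, excess bursting, shared-modulation synchrony,
# theta-band LFP excess and theta-alpha spike-phase locking -- so every
# analysis stage can be exercised without raw recordings.  Every
# generator is a pure function of its parameters and seed.

band_centre <- function(band) mean(band)

#' Simulate an LFP trace with prescribed band content
#'
#' One sinusoid per nonzero band (at the band centre frequency, with a
#' seed-determined random phase) plus white Gaussian noise.
#'
#' @param band_amplitudes Named numeric vector of amplitudes in
#'   microvolts, names matching the configured bands (delta, theta,
#'   alpha, beta, gamma).
#' @param fs Sampling rate in Hz; must be at least 4x the highest
#'   nonzero band edge.
#' @param duration Seconds.
#' @param noise_sd White-noise standard deviation in microvolts.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param bands Band edge table (defaults to [analysis_config] bands).
#' @param region,group Labels for the result.
#' @return An [lfp_signal].
#' @export
simulate_lfp <- function(band_amplitudes, fs, duration, noise_sd = 0,
                         seed = 1L, bands = analysis_config()$bands,
                         region = "RSC", group = "sham_left") {
  stopifnot(all(band_amplitudes >= 0), noise_sd >= 0)
  active <- names(band_amplitudes)[band_amplitudes > 0]
  if (length(active)) {
    top <- max(vapply(bands[active], max, 0))
    if (fs < 4 * top) {
      stop(sprintf("fs = %g Hz too low for a %g Hz band edge (need >= %g)",
                   fs, top, 4 * top), call. = FALSE)
    }
  }
  n <- round(fs * duration)
  t <- (0:(n - 1L)) / fs
  set.seed(seed)
  x <- numeric(n)
  for (nm in names(band_amplitudes)) {
    ph <- stats::runif(1, 0, 2 * pi)   # one draw per band, zero or not
    a <- band_amplitudes[[nm]]
    if (a > 0) x <- x + a * cos(2 * pi * band_centre(bands[[nm]]) * t + ph)
  }
  if (noise_sd > 0) x <- x + stats::rnorm(n, sd = noise_sd)
  lfp_signal(x, fs = fs, region = region, group = group)
}

#' Simulate a spike train with injected bursts
#'
#' Homogeneous Poisson background at `rate` with superimposed burst
#' events: burst onsets are Poisson in time, each burst carries a
#' Poisson-distributed spike count at a fixed intra-burst interspike
#' interval.  The fixed ISI keeps the expected Poisson surprise of an
#' injected burst analytically tractable.
#'
#' @param rate Background rate in Hz (>= 0).
#' @param duration Seconds.
#' @param burst_rate Burst events per minute.
#' @param burst_size_mean Mean spikes per burst (Poisson; bursts that
#'   draw fewer than 2 spikes are dropped).
#' @param intraburst_isi_ms Fixed within-burst ISI in milliseconds.
#' @param seed Integer seed.
#' @param unit_id,region,group Labels.
#' @return A [spike_train] (sorted, deduplicated).
#' @export
simulate_spike_train <- function(rate, duration, burst_rate = 0,
                                 burst_size_mean = 8,
                                 intraburst_isi_ms = 5, seed = 1L,
                                 unit_id = "sim", region = "RSC",
                                 group = "sham_left") {
  if (rate < 0 || burst_rate < 0) stop("rates must be >= 0", call. = FALSE)
  set.seed(seed)
  n_bg <- stats::rpois(1, rate * duration)
  times <- stats::runif(n_bg, 0, duration)
  n_b <- stats::rpois(1, burst_rate / 60 * duration)
  if (n_b > 0) {
    onsets <- stats::runif(n_b, 0, duration)
    sizes <- stats::rpois(n_b, burst_size_mean)
    for (k in seq_len(n_b)) {
      if (sizes[k] < 2L) next
      bt <- onsets[k] + (0:(sizes[k] - 1L)) * intraburst_isi_ms / 1000
      times <- c(times, bt[bt <= duration])
    }
  }
  suppressWarnings(
    spike_train(unit_id, unique(sort(times)), duration,
                region = region, group = group)
  )
}

# Intensity-modulated Poisson sampling by thinning: exact inhomogeneous
# Poisson without discretisation bias.  lambda_fun(t) must be bounded by
# lambda_max.
thin_poisson <- function(lambda_fun, lambda_max, duration) {
  if (lambda_max <= 0) return(numeric())
  n <- stats::rpois(1, lambda_max * duration)
  cand <- sort(stats::runif(n, 0, duration))
  keep <- stats::runif(n) < lambda_fun(cand) / lambda_max
  cand[keep]
}

#' Simulate a spike train phase-locked to an LFP band
#'
#' Inhomogeneous Poisson train whose intensity follows a von Mises
#' density of the band-filtered LFP phase:
#' `lambda(t) = rate * exp(kappa * cos(phase(t) - mu)) / I0(kappa)`,
#' sampled by thinning a Poisson process at the intensity maximum.
#' `kappa = 0` reduces exactly to a homogeneous Poisson train.
#'
#' @param lfp An [lfp_signal].
#' @param band Two-element numeric, Hz; must lie below Nyquist.
#' @param rate Mean rate in Hz.
#' @param kappa von Mises concentration (>= 0).
#' @param preferred_phase Preferred phase in radians (0 = oscillation
#'   peak).
#' @param seed Integer seed.
#' @param unit_id Label.
#' @return A [spike_train] on the LFP's interval.
#' @export
simulate_phase_locked_train <- function(lfp, band = c(4, 12), rate = 5,
                                        kappa = 0, preferred_phase = 0,
                                        seed = 1L, unit_id = "sim") {
  stopifnot(inherits(lfp, "lfp_signal"), kappa >= 0, rate >= 0)
  if (max(band) >= lfp$fs / 2) {
    stop("band outside Nyquist range", call. = FALSE)
  }
  set.seed(seed)
  if (kappa == 0 || rate == 0) {
    times <- sort(stats::runif(stats::rpois(1, rate * lfp$duration),
                               0, lfp$duration))
  } else {
    bp <- band_phase(lfp, band = band)
    i0k <- besselI(kappa, 0, expon.scaled = TRUE)  # I0(kappa) e^-kappa
    lam <- function(tt) {
      idx <- pmin(length(bp$phase), pmax(1L, round(tt * lfp$fs) + 1L))
      rate * exp(kappa * (cos(bp$phase[idx] - preferred_phase) - 1)) / i0k
    }
    lam_max <- rate * exp(0) / i0k   # at cos = 1
    times <- thin_poisson(lam, lam_max, lfp$duration)
  }
  suppressWarnings(
    spike_train(unit_id, unique(times), lfp$duration,
                region = lfp$region, group = lfp$group)
  )
}

# Biphasic extracellular template on an n-sample window: negative
# Gaussian trough at the alignment sample, positive peak (half the
# trough amplitude) ttp_ms later.  Gaussian sigma set so the trough
# full width at half amplitude equals half_width_ms.
waveform_template <- function(ttp_ms, half_width_ms, amplitude_uv,
                              fs = 30000, n_samples = 40L,
                              align_sample = 10L) {
  trough_i <- align_sample
  peak_i <- align_sample + ttp_ms * fs / 1000
  if (peak_i > n_samples) {
    stop(sprintf("trough-to-peak of %g ms exceeds the %d-sample window",
                 ttp_ms, n_samples), call. = FALSE)
  }
  s <- seq_len(n_samples)
  sigma <- half_width_ms / 1000 * fs / (2 * sqrt(2 * log(2)))  # FWHM -> sd
  sigma_p <- sigma * 1.5
  -amplitude_uv * exp(-((s - trough_i)^2) / (2 * sigma^2)) +
    0.5 * amplitude_uv * exp(-((s - peak_i)^2) / (2 * sigma_p^2))
}

#' Simulate a set of spike waveforms
#'
#' Replicates a biphasic template (trough at the alignment sample, peak
#' `ttp_ms` later, trough width at half amplitude `half_width_ms`)
#' across `n_events` events and 4 tetrode channels with fixed
#' per-channel gains, plus additive Gaussian noise.
#'
#' @param ttp_ms Trough-to-peak time, ms.
#' @param half_width_ms Trough width at half amplitude, ms.
#' @param amplitude_uv Trough amplitude, microvolts.
#' @param n_events Number of events.
#' @param noise_sd Additive noise sd, microvolts.
#' @param fs Sampling rate (default 30 kHz).
#' @param seed Integer seed.
#' @param n_samples,align_sample Window geometry (40 samples, crossing
#'   at sample 10).
#' @return A `waveform_set`: list with `waves`
#'   (events x channels x samples array), `fs`, `align_sample`.
#' @export
simulate_waveform_set <- function(ttp_ms, half_width_ms = 0.25,
                                  amplitude_uv = 100, n_events = 100L,
                                  noise_sd = 0, fs = 30000, seed = 1L,
                                  n_samples = 40L, align_sample = 10L) {
  tpl <- waveform_template(ttp_ms, half_width_ms, amplitude_uv,
                           fs = fs, n_samples = n_samples,
                           align_sample = align_sample)
  gains <- c(1, 0.8, 0.6, 0.4)
  set.seed(seed)
  waves <- array(0, dim = c(n_events, 4L, n_samples))
  for (ev in seq_len(n_events)) {
    for (ch in 1:4) {
      waves[ev, ch, ] <- gains[ch] * tpl +
        if (noise_sd > 0) stats::rnorm(n_samples, sd = noise_sd) else 0
    }
  }
  new_waveform_set(waves, fs = fs, align_sample = align_sample)
}

#' Cohort specification for the synthetic generator
#'
#' Defaults encode the model system's group structure: ipsilateral groups carry
#' about half the units of each sham hemisphere, reduced pyramidal
#' firing rates, an elevated burst injection rate, a shared slow rate
#' modulation driving pairwise synchrony, theta-band LFP excess, and
#' theta-alpha spike-phase concentration; the sham and contralateral
#' groups are baseline.
#'
#' @param n_units Named integer vector, units per group (per region).
#' @param rate_hz Named numeric, pyramidal background rate per group.
#' @param burst_rate_min Named numeric, injected bursts per minute.
#' @param burst_size_mean Mean spikes per injected burst.
#' @param intraburst_isi_ms Fixed within-burst ISI, ms.
#' @param shared_modulation Named numeric in [0, 1]: strength of the
#'   slow log-rate modulation shared across a group's units.
#' @param kappa Named numeric >= 0: von Mises concentration of spike
#'   phase in the coupling band.
#' @param preferred_phase Radians.
#' @param theta_uv Named numeric: theta-band LFP amplitude per group.
#' @param base_band_uv Baseline amplitude of every band.
#' @param lfp_noise_sd LFP white-noise sd, microvolts.
#' @param duration Seconds per session.
#' @param lfp_fs LFP sampling rate, Hz.
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_units = c(sham_left = 10, sham_right = 10,
                                    hi_contra = 10, hi_ipsi = 5),
                        rate_hz = c(sham_left = 5, sham_right = 5,
                                    hi_contra = 5, hi_ipsi = 2.5),
                        burst_rate_min = c(sham_left = 1, sham_right = 1,
                                           hi_contra = 1, hi_ipsi = 6),
                        burst_size_mean = 8,
                        intraburst_isi_ms = 5,
                        shared_modulation = c(sham_left = 0, sham_right = 0,
                                              hi_contra = 0, hi_ipsi = 0.8),
                        kappa = c(sham_left = 0, sham_right = 0,
                                  hi_contra = 0, hi_ipsi = 4),
                        preferred_phase = 0,
                        theta_uv = c(sham_left = 10, sham_right = 10,
                                     hi_contra = 10, hi_ipsi = 30),
                        base_band_uv = 5,
                        lfp_noise_sd = 5,
                        duration = 300,
                        lfp_fs = 500,
                        seed = 1L) {
  groups <- c("sham_left", "sham_right", "hi_contra", "hi_ipsi")
  spec <- list(n_units = n_units, rate_hz = rate_hz,
               burst_rate_min = burst_rate_min,
               burst_size_mean = burst_size_mean,
               intraburst_isi_ms = intraburst_isi_ms,
               shared_modulation = shared_modulation, kappa = kappa,
               preferred_phase = preferred_phase, theta_uv = theta_uv,
               base_band_uv = base_band_uv, lfp_noise_sd = lfp_noise_sd,
               duration = duration, lfp_fs = lfp_fs, seed = as.integer(seed))
  for (nm in c("n_units", "rate_hz", "burst_rate_min", "shared_modulation",
               "kappa", "theta_uv")) {
    if (!all(groups %in% names(spec[[nm]]))) {
      stop(sprintf("`%s` must name all four groups", nm), call. = FALSE)
    }
    if (any(spec[[nm]] < 0)) stop(sprintf("`%s` must be >= 0", nm),
                                  call. = FALSE)
  }
  if (any(shared_modulation > 1)) {
    stop("shared_modulation must be in [0, 1]", call. = FALSE)
  }
  structure(spec, class = "cohort_spec")
}

# Slow (~1 Hz bandwidth) zero-mean unit-variance modulation series used
# as the shared log-rate drive for within-group synchrony.
slow_modulation <- function(n, fs, bandwidth_hz = 1) {
  x <- stats::rnorm(n)
  sigma <- fs / (2 * pi * bandwidth_hz)
  half <- ceiling(4 * sigma)
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  sm <- stats::filter(c(rev(x[1:half]), x, rev(x[(n - half + 1):n])),
                      k, sides = 2)
  sm <- as.numeric(sm)[(half + 1):(half + n)]
  (sm - mean(sm)) / stats::sd(sm)
}

#' Simulate a full recording cohort
#'
#' Generates, for each of the four hemisphere groups and both regions,
#' one LFP trace and `n_units` spike trains combining a background rate,
#' injected bursts, a shared slow rate modulation (pairwise synchrony),
#' and von Mises phase locking to the group LFP in the 4-12 Hz band,
#' plus an averaged waveform per unit drawn from a pyramidal/interneuron
#' mixture.
#'
#' @param spec A [cohort_spec].
#' @param regions Regions to simulate (default both).
#' @return A list of class `cohort` with elements `trains` (named list
#'   of [spike_train]), `lfps` (named list of [lfp_signal], one per
#'   group x region), `units` (data frame of per-unit ground truth:
#'   group, region, true ttp/half-width, cell class), `waveforms`
#'   (named list of `waveform_set`), and `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), regions = c("RSC", "HPC")) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c("sham_left", "sham_right", "hi_contra", "hi_ipsi")
  bands0 <- analysis_config()$bands
  trains <- list()
  lfps <- list()
  waveforms <- list()
  units <- list()
  seed0 <- spec$seed
  for (rg in regions) {
    for (g in groups) {
      key <- paste(g, rg, sep = ".")
      amp <- c(delta = spec$base_band_uv, theta = spec$base_band_uv,
               alpha = spec$base_band_uv, beta = spec$base_band_uv,
               gamma = spec$base_band_uv)
      amp["theta"] <- spec$theta_uv[[g]]
      seed_lfp <- seed0 + 1000L * match(rg, c("RSC", "HPC")) + match(g, groups)
      lfps[[key]] <- simulate_lfp(amp, fs = spec$lfp_fs,
                                  duration = spec$duration,
                                  noise_sd = spec$lfp_noise_sd,
                                  seed = seed_lfp, region = rg, group = g)
      n_u <- spec$n_units[[g]]
      if (n_u == 0) next
      # phase series of the group LFP (coupling drive) and shared slow
      # modulation, both fixed per group/region
      bp <- band_phase(lfps[[key]], band = c(4, 12))
      set.seed(seed_lfp + 7L)
      mod <- slow_modulation(length(lfps[[key]]$samples), spec$lfp_fs)
      s_mod <- spec$shared_modulation[[g]]
      kap <- spec$kappa[[g]]
      i0k <- besselI(kap, 0, expon.scaled = TRUE)
      fs_l <- spec$lfp_fs
      for (u in seq_len(n_u)) {
        uid <- sprintf("%s_%s_u%02d", g, rg, u)
        useed <- seed_lfp + 100000L + 97L * u
        set.seed(useed)
        rate <- spec$rate_hz[[g]]
        lam <- function(tt) {
          idx <- pmin(length(mod), pmax(1L, round(tt * fs_l) + 1L))
          rate * exp(s_mod * mod[idx] - s_mod^2 / 2) *
            exp(kap * (cos(bp$phase[idx] - spec$preferred_phase) - 1)) / i0k
        }
        lam_max <- rate * exp(s_mod * max(mod) - s_mod^2 / 2) / i0k
        bg <- thin_poisson(lam, lam_max, spec$duration)
        # injected bursts
        n_b <- stats::rpois(1, spec$burst_rate_min[[g]] / 60 * spec$duration)
        if (n_b > 0) {
          onsets <- stats::runif(n_b, 0, spec$duration)
          sizes <- stats::rpois(n_b, spec$burst_size_mean)
          for (k in seq_len(n_b)) {
            if (sizes[k] < 2L) next
            bt <- onsets[k] + (0:(sizes[k] - 1L)) * spec$intraburst_isi_ms / 1000
            bg <- c(bg, bt[bt <= spec$duration])
          }
        }
        trains[[uid]] <- suppressWarnings(
          spike_train(uid, unique(sort(bg)), spec$duration,
                      region = rg, group = g))
        # 90% pyramidal-like, 10% interneuron-like waveforms
        thr <- if (rg == "RSC") 0.4 else 0.25
        is_in <- stats::runif(1) < 0.1
        ttp <- if (is_in) max(0.1, stats::rnorm(1, 0.6 * thr, 0.05 * thr))
               else stats::rnorm(1, 1.6 * thr, 0.15 * thr)
        hw <- if (is_in) 0.15 else 0.3
        waveforms[[uid]] <- simulate_waveform_set(
          ttp_ms = ttp, half_width_ms = hw, amplitude_uv = 100,
          n_events = 50L, noise_sd = 5, seed = useed + 1L)
        units[[uid]] <- data.frame(unit_id = uid, group = g, region = rg,
                                   true_ttp_ms = ttp, true_half_width_ms = hw,
                                   true_class = if (is_in) "IN" else "PN",
                                   stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(trains = trains, lfps = lfps, waveforms = waveforms,
                 units = do.call(rbind, c(units, make.row.names = FALSE)),
                 spec = spec),
            class = "cohort")
}

#' Simulate a 7-day rotarod learning series
#'
#' Per-unit, per-session mean spike-field coherence over `n_days` x
#' `trials_per_day` sessions: reactive units ramp linearly from low to
#' high coherence across sessions, non-reactive units stay constant
#' low, and HI-affected units stay constant high with low correlation
#' to the task state.  Latency to fall ramps toward the 300 s cap in
#' sham animals and stays flat in HI animals.
#'
#' @param n_days,trials_per_day Protocol shape (7 days x 3 trials).
#' @param n_reactive,n_nonreactive,n_affected Units per true class.
#' @param noise_sd Session-to-session coherence noise.
#' @param seed Integer seed.
#' @return A list of class `session_series_set`: `sessions` data frame
#'   (unit_id, true_label, group, day, trial, session, task_on,
#'   coherence) and `latency` data frame (group, day, trial, latency_s).
#' @export
simulate_learning_series <- function(n_days = 7L, trials_per_day = 3L,
                                     n_reactive = 10L, n_nonreactive = 10L,
                                     n_affected = 5L, noise_sd = 0.04,
                                     seed = 1L) {
  stopifnot(n_reactive >= 0, n_nonreactive >= 0, n_affected >= 0)
  set.seed(seed)
  n_sessions <- n_days * trials_per_day
  sess_idx <- seq_len(n_sessions)
  day <- rep(seq_len(n_days), each = trials_per_day)
  trial <- rep(seq_len(trials_per_day), times = n_days)
  labels <- c(rep("reactive", n_reactive),
              rep("non_reactive", n_nonreactive),
              rep("affected", n_affected))
  grp <- c(rep("sham_left", n_reactive + n_nonreactive),
           rep("hi_ipsi", n_affected))
  rows <- vector("list", length(labels))
  for (u in seq_along(labels)) {
    base <- switch(labels[u],
      reactive = 0.1 + 0.5 * (sess_idx - 1) / (n_sessions - 1),
      non_reactive = rep(0.15, n_sessions),
      affected = rep(0.6, n_sessions))
    coh <- pmax(0, pmin(1, base + stats::rnorm(n_sessions, sd = noise_sd)))
    # affected units: coherence unrelated to task state; others get a
    # small task-on increment on top of the trend
    task_on <- rep(TRUE, n_sessions)
    rows[[u]] <- data.frame(
      unit_id = sprintf("trk_u%02d", u), true_label = labels[u],
      group = grp[u], day = day, trial = trial, session = sess_idx,
      task_on = task_on, coherence = coh, stringsAsFactors = FALSE)
  }
  lat <- rbind(
    data.frame(group = "sham_left", day = day, trial = trial,
               latency_s = pmin(300, 80 + 220 * (sess_idx - 1) /
                                  (n_sessions - 1) +
                                  stats::rnorm(n_sessions, sd = 15))),
    data.frame(group = "hi_ipsi", day = day, trial = trial,
               latency_s = pmax(5, pmin(300, 80 +
                                  stats::rnorm(n_sessions, sd = 15)))))
  structure(list(sessions = do.call(rbind, rows), latency = lat,
                 n_days = n_days, trials_per_day = trials_per_day),
            class = "session_series_set")
}
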