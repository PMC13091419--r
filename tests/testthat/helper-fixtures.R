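# Shared fixtures and independent oracles used across the suite.

# von Mises sampler by rejection from the uniform envelope; independent
# of the package's thinning-based generator.
rvonmises <- function(n, mu, kappa) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::runif(n, 0, 2 * pi)
    keep <- stats::runif(n) < exp(kappa * (cos(x - mu) - 1))
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

# Brute-force Poisson upper-tail surprise: direct summation of the
# density, independent of ppois.
surprise_bruteforce <- function(n, T, r) {
  if (n == 0) return(0)
  lambda <- r * T
  kmax <- max(n + 60L, ceiling(lambda + 40 * sqrt(lambda) + 60))
  p_tail <- sum(stats::dpois(n:kmax, lambda))
  -log(p_tail)
}

# Exhaustive surprise maximization over all contiguous spike windows of
# >= 3 spikes; returns c(i, j, max_surprise).
exhaustive_best_burst <- function(times, duration) {
  n <- length(times)
  r <- n / duration
  best <- c(0, 0, 0)
  for (i in 1:(n - 2L)) {
    for (j in (i + 2L):n) {
      T <- times[j] - times[i]
      if (T > 0) {
        s <- poisson_surprise(j - i + 1L, T, r)
        if (s > best[3L]) best <- c(i, j, s)
      }
    }
  }
  best
}

# Random test train: uniform spikes, optionally with an injected fast
# run, as used for detector/oracle agreement.
random_train <- function(n, duration, inject = FALSE) {
  tt <- sort(stats::runif(n, 0, duration))
  if (inject) {
    m <- sample(3:8, 1)
    o <- stats::runif(1, 0, duration * 0.8)
    tt <- sort(unique(c(tt, o + (0:(m - 1)) * 0.01)))
  }
  suppressWarnings(spike_train("rnd", tt, duration))
}

# A pure theta-dominated LFP used by several phase/field tests.
theta_lfp <- function(fs = 500, duration = 60, theta = 10, noise = 0,
                      seed = 1) {
  simulate_lfp(c(delta = 0, theta = theta, alpha = 0, beta = 0, gamma = 0),
               fs = fs, duration = duration, noise_sd = noise, seed = seed)
}

# Synthetic tracked unit: peak-channel mean waveform + spike train.
tracked_unit <- function(ttp, hw, rate, burst_rate, seed, duration = 300) {
  ws <- simulate_waveform_set(ttp, hw, 100, n_events = 60, noise_sd = 8,
                              seed = seed)
  list(w = average_waveform(ws)[1, ],
       tr = simulate_spike_train(rate, duration, burst_rate = burst_rate,
                                 seed = seed))
}

# Reference cohort unit counts (PN, IN) per group and region.
reference_cohort_counts <- list(
  "sham_left.RSC" = c(PN = 49, IN = 6),
  "sham_right.RSC" = c(PN = 57, IN = 11),
  "hi_contra.RSC" = c(PN = 120, IN = 13),
  "hi_ipsi.RSC" = c(PN = 89, IN = 9),
  "sham_left.HPC" = c(PN = 53, IN = 11),
  "sham_right.HPC" = c(PN = 75, IN = 16),
  "hi_contra.HPC" = c(PN = 158, IN = 18),
  "hi_ipsi.HPC" = c(PN = 35, IN = 6))
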