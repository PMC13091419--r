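test_that("band phase follows the cosine convention on a pure tone", {
  tone <- theta_lfp(fs = 500, duration = 40, noise = 0, seed = 1)
  bp <- band_phase(tone, c(4, 12))
  # phase at raw maxima is 0 (mod 2pi), at minima pi
  core <- 2000:18000
  pk <- core[which.max(tone$samples[core])]
  tr <- core[which.min(tone$samples[core])]
  circ_dist <- function(a, b) abs(Arg(exp(1i * (a - b))))
  expect_lt(circ_dist(bp$phase[pk], 0), 0.1)
  expect_lt(circ_dist(bp$phase[tr], pi), 0.1)

  # unwrapped slope ~ 2*pi*6 rad/s
  ph <- bp$phase[5000:10000]
  slope <- mean((diff(ph) + pi) %% (2 * pi) - pi) * 500
  expect_equal(slope, 2 * pi * 6, tolerance = 0.01)

  expect_error(band_phase(lfp_signal(rep(1, 4096), 500)), "constant")
  expect_error(band_phase(theta_lfp(), c(4, 400)), "Nyquist")
})

test_that("spike phases read off the series at spike times", {
  tone <- theta_lfp(fs = 500, duration = 40, noise = 0, seed = 2)
  bp <- band_phase(tone, c(4, 12))
  ext <- function(s) {
    i <- which(diff(sign(diff(tone$samples))) == s) + 1
    i[i > 1000 & i < 19000]          # clear of filter edge transients
  }
  peaks <- ext(-2)
  troughs <- ext(2)
  ang_pk <- spike_phases(spike_train("p", peaks / 500, 40), bp)
  ang_tr <- spike_phases(spike_train("t", troughs / 500, 40), bp)
  expect_lt(max(abs(Arg(exp(1i * ang_pk)))), 0.15)
  expect_lt(max(abs(Arg(exp(1i * (ang_tr - pi))))), 0.15)
  expect_length(spike_phases(spike_train("e", numeric(), 40), bp), 0L)
  # a spike at the recording end clamps to the last sample...
  last <- spike_phases(spike_train("z", 40, 40), bp)
  expect_equal(last, bp$phase[length(bp$phase)])
  # ...but spikes beyond the series error with their indices
  short <- list(phase = bp$phase[1:10000], fs = 500)
  expect_error(spike_phases(spike_train("x", c(1, 39), 40), short),
               "outside the LFP interval at indices: 2")
})

test_that("PLV matches constructed samples and the von Mises oracle", {
  expect_equal(plv(rep(pi / 4, 10)),
               list(plv = 1, mean_angle = pi / 4), tolerance = 1e-12)
  # 8 uniformly spaced angles cancel
  expect_lt(plv(seq(0, 2 * pi, length.out = 9)[1:8])$plv, 1e-12)
  # von Mises kappa = 2: PLV ~ I1(2)/I0(2) ~ 0.698
  set.seed(21)
  a <- rvonmises(1e5, pi, 2)
  expect_equal(plv(a)$plv, besselI(2, 1) / besselI(2, 0),
               tolerance = 0.02)
  expect_error(plv(numeric()), "empty")
})

test_that("PLV rotates equivariantly; mean angle follows", {
  set.seed(22)
  a <- rvonmises(2000, 1, 3)
  v0 <- plv(a)
  v1 <- plv(a + 0.7)
  expect_equal(v1$plv, v0$plv, tolerance = 1e-12)
  expect_equal((v1$mean_angle - v0$mean_angle) %% (2 * pi), 0.7,
               tolerance = 1e-9)
})

test_that("Rayleigh statistics satisfy Z = n PLV^2 and calibrate under the null", {
  # degenerate concentration: Z = n, vanishing p
  rt <- rayleigh_test(rep(1.2, 50))
  expect_equal(rt$Z, 50, tolerance = 1e-9)
  expect_lt(rt$p, 1e-20)
  # PLV ~ 0: Z ~ 0, p ~ 1
  rt0 <- rayleigh_test(seq(0, 2 * pi, length.out = 101)[1:100])
  expect_lt(rt0$Z, 1e-10)
  expect_gt(rt0$p, 0.99)
  # null calibration: uniform samples give roughly uniform p
  set.seed(23)
  ps <- replicate(200, rayleigh_test(runif(500, 0, 2 * pi))$p)
  expect_gte(mean(ps > 0.05), 0.9)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_warning(rayleigh_test(rep(1, 5)), "n < 10")
})

test_that("phase histograms conserve counts", {
  set.seed(24)
  a <- runif(1000, 0, 2 * pi)
  h <- phase_histogram(a, 18)
  expect_equal(sum(h$count), 1000L)
  # uniform grid sample: equal counts
  g <- phase_histogram(seq(0, 2 * pi, length.out = 181)[1:180], 18)
  expect_true(all(g$count == 10L))
  # all-equal sample: single nonzero bin
  s <- phase_histogram(rep(2, 40), 18)
  expect_equal(sum(s$count > 0), 1L)
  expect_error(phase_histogram(a, 3), "bins")
})

test_that("modulation index hits its exact extremes and matches a brute-force oracle", {
  ph <- seq(0, 2 * pi, length.out = 36001)[1:36000]
  # uniform envelope: maximum entropy, MI = 0
  expect_equal(modulation_index(ph, rep(2.5, 36000)), 0, tolerance = 1e-12)
  # single-bin envelope: zero entropy, MI = 1
  env1 <- as.numeric(ph < 2 * pi / 18)
  expect_equal(modulation_index(ph, env1), 1, tolerance = 1e-12)
  # cosine-modulated envelope vs an independent binning implementation
  # (random phases so no sample sits on a bin boundary)
  set.seed(77)
  ph <- runif(36000, 0, 2 * pi)
  env <- 1 + cos(ph)
  mi_oracle <- local({
    nb <- 18
    bin <- floor(ph / (2 * pi) * nb) + 1
    means <- tapply(env, bin, mean)
    pj <- means / sum(means)
    (log(nb) + sum(pj * log(pj))) / log(nb)
  })
  expect_equal(modulation_index(ph, env), as.numeric(mi_oracle),
               tolerance = 1e-12)
  expect_error(modulation_index(ph, rep(0, 36000)), "zero")
})

test_that("modulation index is scale-invariant and monotone in depth", {
  ph <- seq(0, 2 * pi, length.out = 7201)[1:7200]
  env <- 1 + 0.5 * cos(ph)
  expect_equal(modulation_index(ph, env), modulation_index(ph, 37 * env),
               tolerance = 1e-12)
  mis <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(d) {
    modulation_index(ph, 1 + d * cos(ph))
  }, 0)
  expect_true(all(diff(mis) > 0))
})

test_that("phase_stats aggregates concentration that grows with coupling", {
  lfp <- theta_lfp(duration = 300, noise = 2, seed = 25)
  locked <- simulate_phase_locked_train(lfp, rate = 8, kappa = 4, seed = 1)
  flat <- simulate_phase_locked_train(lfp, rate = 8, kappa = 0, seed = 2)
  sl <- phase_stats(locked, lfp)
  sf <- phase_stats(flat, lfp)
  expect_gt(sl$plv, sf$plv)
  expect_gt(sl$mi, sf$mi)
  expect_lt(sl$rayleigh_p, 0.001)
  expect_gt(sf$rayleigh_p, 0.001)
})
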