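test_that("correlograms place mass at constructed lags", {
  # periodic train: autocorrelogram peaks at multiples of 100 ms
  per <- spike_train("p", seq(0.1, 60, by = 0.1), 60)
  ac <- correlogram(per, bin_ms = 5, max_lag_ms = 250)
  peaks <- ac$lag_ms[ac$count > 0]
  expect_true(all(abs(peaks) %% 100 < 5 | abs(peaks) %% 100 > 95))
  # zero-lag bins exclude self pairs
  near0 <- which(abs(ac$lag_ms) < 5)
  expect_true(all(ac$count[near0] == 0))

  # shifted copy: cross-correlogram peak at +20 ms
  a <- simulate_spike_train(5, 100, seed = 3)
  b <- spike_train("b", a$times[a$times < 99.9] + 0.02, 100)
  cc <- correlogram(a, b, bin_ms = 5, max_lag_ms = 100)
  expect_equal(cc$lag_ms[which.max(cc$count)], 22.5)

  # empty train gives an all-zero correlogram
  e <- spike_train("e", numeric(), 10)
  expect_true(all(correlogram(a, e)$count == 0))
})

test_that("correlogram reversal symmetry holds between train orders", {
  a <- simulate_spike_train(4, 200, seed = 5)
  b <- simulate_spike_train(4, 200, seed = 6)
  ab <- correlogram(a, b, bin_ms = 4, max_lag_ms = 80)
  ba <- correlogram(b, a, bin_ms = 4, max_lag_ms = 80)
  expect_equal(ab$count, rev(ba$count))
})

test_that("independent Poisson trains give flat correlograms", {
  a <- simulate_spike_train(10, 1000, seed = 7)
  b <- simulate_spike_train(10, 1000, seed = 8)
  cc <- correlogram(a, b, bin_ms = 5, max_lag_ms = 100)
  expect_lt(max(cc$count) / mean(cc$count), 1.5)
})

test_that("binned rates conserve counts and smooth correctly", {
  tr <- spike_train("u", c(0.001, 0.004, 0.008, 0.012) - 0.0005 + 0.0005,
                    duration = 1)
  r <- binned_rate(tr, bin_ms = 12.5, smooth_sigma_ms = 0)
  expect_equal(r[1], 4 / 0.0125)     # 4 spikes in the first bin = 320 Hz
  expect_equal(sum(r) * 0.0125, 4)   # count conserved
  # empty train: all-zero series of the right length
  e <- spike_train("e", numeric(), 1)
  expect_equal(as.numeric(binned_rate(e, 12.5, 0)), rep(0, 80))
  # sigma 0 is the identity; smoothing approximately conserves mass
  tr2 <- simulate_spike_train(5, 60, seed = 2)
  r0 <- binned_rate(tr2, 12.5, 0)
  rs <- binned_rate(tr2, 12.5, 25)
  expect_equal(sum(rs), sum(r0), tolerance = 0.01)
})

test_that("spike-spike coherence is calibrated against known structure", {
  a <- simulate_spike_train(10, 600, seed = 1)
  # identical trains: coherence 1 everywhere
  self <- spike_spike_coherence(a, a)
  expect_true(all(abs(self$coherence - 1) < 1e-9))
  # independent trains: low mean coherence
  b <- simulate_spike_train(10, 600, seed = 2)
  expect_lt(spike_spike_coherence(a, b)$mean_coherence, 0.1)
  # shared 6 Hz rate modulation: coherence peak inside 4-8 Hz
  lfp <- theta_lfp(duration = 600, noise = 0, seed = 9)
  t1 <- simulate_phase_locked_train(lfp, rate = 20, kappa = 3, seed = 4)
  t2 <- simulate_phase_locked_train(lfp, rate = 20, kappa = 3, seed = 5)
  ch <- spike_spike_coherence(t1, t2, nfft = 512)
  pk <- ch$freq[ch$freq > 0.5][which.max(ch$coherence[ch$freq > 0.5])]
  expect_gte(pk, 4)
  expect_lte(pk, 8)
  expect_error(spike_spike_coherence(
    spike_train("x", c(0.01, 0.05), 0.1),
    spike_train("y", c(0.02), 0.1)), "block")
})

test_that("pairwise R2 matrices behave under nulls, duplicates, and relabeling", {
  set.seed(12)
  trains <- lapply(1:6, function(i) simulate_spike_train(5, 600, seed = i))
  rates <- lapply(trains, binned_rate)
  names(rates) <- paste0("u", 1:6)
  M <- pairwise_r2_matrix(rates)
  expect_true(all(diag(M) == 1))
  expect_true(all(M >= 0 & M <= 1))
  expect_equal(M, t(M))
  expect_lt(median(M[upper.tri(M)]), 0.05)

  # duplicated series: off-diagonal entry exactly 1
  rates2 <- rates
  rates2$u2 <- rates2$u1
  M2 <- pairwise_r2_matrix(rates2)
  expect_equal(M2["u1", "u2"], 1)

  # permutation equivariance
  perm <- c(3, 1, 2, 6, 5, 4)
  Mp <- pairwise_r2_matrix(rates[perm])
  expect_equal(Mp, M[perm, perm])

  # zero-variance series warns and yields 0
  rates3 <- rates
  rates3$u3 <- structure(rep(0, length(rates$u1)), bin_ms = 12.5)
  expect_warning(M3 <- pairwise_r2_matrix(rates3), "zero-variance")
  expect_equal(M3["u3", "u1"], 0)
})

test_that("shared slow modulation elevates pairwise R2 above independents", {
  co <- simulate_cohort(cohort_spec(duration = 120), regions = "RSC")
  grp <- co$units$group[match(names(co$trains), co$units$unit_id)]
  r2_of <- function(g) {
    rates <- lapply(co$trains[grp == g], binned_rate)
    M <- pairwise_r2_matrix(rates)
    median(M[upper.tri(M)])
  }
  expect_gt(r2_of("hi_ipsi"), r2_of("sham_left"))
})

test_that("cluster ordering keeps blocks contiguous and is stable on ties", {
  ids <- paste0("u", 1:6)
  M <- diag(6)
  dimnames(M) <- list(ids, ids)
  expect_equal(cluster_order(M), ids)      # tie-break: input order

  M2 <- matrix(0.05, 6, 6, dimnames = list(ids, ids))
  M2[1:3, 1:3] <- 0.9
  M2[4:6, 4:6] <- 0.9
  diag(M2) <- 1
  ord <- cluster_order(M2)
  g1 <- match(paste0("u", 1:3), ord)
  g2 <- match(paste0("u", 4:6), ord)
  expect_equal(max(g1) - min(g1), 2L)      # each block contiguous
  expect_equal(max(g2) - min(g2), 2L)

  # noisy two-cluster recovery: Rand index vs truth > 0.9
  set.seed(13)
  truth <- rep(1:2, each = 8)
  base <- outer(truth, truth, function(a, b) ifelse(a == b, 0.8, 0.1))
  noise <- matrix(runif(256, -0.05, 0.05), 16)
  Mn <- base + (noise + t(noise)) / 2
  Mn[Mn < 0] <- 0
  Mn[Mn > 1] <- 1
  diag(Mn) <- 1
  dimnames(Mn) <- list(paste0("n", 1:16), paste0("n", 1:16))
  ord <- cluster_order(Mn)
  # cut the leaf order in half and compare to truth via the Rand index
  half <- match(rownames(Mn), ord) <= 8
  pair_same <- function(lab) {
    m <- outer(lab, lab, "==")
    m[upper.tri(m)]
  }
  rand <- mean(pair_same(half) == pair_same(truth))
  expect_gt(rand, 0.9)
})

test_that("matrix similarity reflects identity, inversion and permutation nulls", {
  set.seed(14)
  ids <- paste0("u", 1:12)
  M <- matrix(runif(144), 12, dimnames = list(ids, ids))
  M <- (M + t(M)) / 2
  diag(M) <- 1
  expect_equal(matrix_similarity(M, M), 1)
  Minv <- 1 - M
  diag(Minv) <- 1
  dimnames(Minv) <- dimnames(M)
  expect_equal(matrix_similarity(M, Minv), -1)
  # random permutation of the off-diagonal entries decorrelates
  Mp <- M
  ut <- which(upper.tri(M))
  Mp[ut] <- M[sample(ut)]
  Mp[lower.tri(Mp)] <- t(Mp)[lower.tri(Mp)]
  expect_lt(abs(matrix_similarity(M, Mp)), 0.3)
  expect_error(matrix_similarity(M, M[1:6, 1:6]), "unit set")
})
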