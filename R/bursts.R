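#' Poisson surprise of a spike window
#'
#' The surprise of observing `n` spikes in `T` seconds against a
#' homogeneous Poisson null at rate `r` is `S = -ln Pr[N >= n]` with
#' `N ~ Poisson(rT)`: the negative logarithm of the firing probability.
#' Computed on the log scale via the regularized upper Poisson tail, so
#' it is stable far into the tail (S of hundreds).
#'
#' @param n Spike count (>= 0), vectorised.
#' @param T Window length in seconds (> 0).
#' @param r Baseline rate in Hz (> 0).
#' @return Surprise value(s) `S >= 0`; `n = 0` gives `S = 0`.
#' @export
poisson_surprise <- function(n, T, r) {
  if (any(T <= 0)) stop("window length T must be > 0", call. = FALSE)
  if (any(r <= 0)) stop("baseline rate r must be > 0", call. = FALSE)
  if (any(n < 0)) stop("spike count n must be >= 0", call. = FALSE)
  # Pr[N >= n] = Pr[N > n - 1]; log.p keeps precision in the deep tail
  s <- -stats::ppois(n - 1, lambda = r * T, lower.tail = FALSE, log.p = TRUE)
  pmax(0, s)
}

# Surprise of the contiguous spike window i..j of `times` (1-based,
# inclusive); duration is last - first spike time.
window_surprise <- function(times, i, j, r) {
  T <- times[j] - times[i]
  if (T <= 0) return(0)
  poisson_surprise(j - i + 1L, T, r)
}

#' Detect bursts by the Legendy-Salcman Poisson-surprise method
#'
#' Seeds candidate bursts at runs of consecutive interspike intervals
#' shorter than half the train's mean ISI, then alternately re-optimises
#' the burst end (over all forward extensions) and the burst start until
#' the surprise no longer increases.  A candidate is accepted when its
#' final surprise reaches `surprise_threshold`; overlapping accepted
#' bursts are merged (the merged window is kept when it still clears the
#' threshold, otherwise the best constituent is kept).
#'
#' @param train A [spike_train] with at least 3 spikes (fewer gives an
#'   empty burst set).
#' @param surprise_threshold Minimum Poisson surprise for acceptance
#'   (protocol value 5, i.e. tail probability below `exp(-5)`).
#' @param min_spikes Minimum spikes per burst (default 3).
#' @return A `burst_set`: data frame with columns `start_s`, `end_s`,
#'   `n_spikes`, `surprise`, plus attributes `unit_id` and `train`.
#' @export
detect_bursts <- function(train, surprise_threshold = 5, min_spikes = 3L) {
  stopifnot(inherits(train, "spike_train"))
  times <- train$times
  n <- length(times)
  empty <- data.frame(start_s = numeric(), end_s = numeric(),
                      n_spikes = integer(), surprise = numeric())
  if (n < min_spikes) return(new_burst_set(empty, train))
  r <- n / train$duration
  isi <- diff(times)
  short <- isi < mean(isi) / 2

  # seed windows: (a) each maximal run of short ISIs, (b) the
  # highest-surprise consecutive spike triplets (catches clusters whose
  # ISIs are not short relative to the train-wide mean ISI)
  seed_win <- list()
  if (any(short)) {
    rl <- rle(short)
    run_end <- cumsum(rl$lengths)
    run_start <- run_end - rl$lengths + 1L
    for (k in which(rl$values)) {
      seed_win[[length(seed_win) + 1L]] <-
        c(run_start[k], min(n, run_end[k] + 1L))
    }
  }
  if (n >= 3L) {
    i3 <- 1:(n - 2L)
    s3 <- poisson_surprise(3L, pmax(times[i3 + 2L] - times[i3], 1e-12), r)
    hot <- i3[s3 >= min(2, surprise_threshold / 2)]
    hot <- hot[order(s3[match(hot, i3)], decreasing = TRUE)]
    for (i in utils::head(hot, 20L)) {
      seed_win[[length(seed_win) + 1L]] <- c(i, i + 2L)
    }
  }
  if (!length(seed_win)) return(new_burst_set(empty, train))

  # surprise of [i, j] vectorised over one margin
  surprise_vec <- function(nn, TT) {
    s <- -stats::ppois(nn - 1, lambda = r * pmax(TT, 1e-300),
                       lower.tail = FALSE, log.p = TRUE)
    s[TT <= 0] <- 0
    pmax(0, s)
  }
  # bursts are local events: the per-coordinate search is bounded to a
  # 200-spike horizon beyond the current window (iterated ascent can
  # still grow past it)
  horizon <- 200L
  best_end <- function(i, j_cur) {
    j_cand <- (i + min_spikes - 1L):min(n, max(j_cur, i) + horizon)
    s <- surprise_vec(j_cand - i + 1L, times[j_cand] - times[i])
    j_cand[which.max(s)]
  }
  best_start <- function(j, i_cur) {
    i_cand <- max(1L, min(i_cur, j) - horizon):(j - min_spikes + 1L)
    s <- surprise_vec(j - i_cand + 1L, times[j] - times[i_cand])
    i_cand[which.max(s)]
  }

  cand <- list()
  seen <- character()
  for (sw in seed_win) {
    i <- sw[1L]
    j <- max(sw[2L], i + min_spikes - 1L)
    if (j > n) next
    for (iter in 1:50) {            # fixed point reached in a few passes
      j2 <- best_end(i, j)
      i2 <- best_start(j2, i)
      if (i2 == i && j2 == j) break
      i <- i2; j <- j2
    }
    key <- paste(i, j)
    if (key %in% seen) next
    seen <- c(seen, key)
    s <- window_surprise(times, i, j, r)
    if (s >= surprise_threshold) cand[[length(cand) + 1L]] <- c(i, j, s)
  }
  if (!length(cand)) return(new_burst_set(empty, train))

  cand <- unique(do.call(rbind, cand))
  cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]

  # merge overlapping accepted windows
  merged <- list()
  cur <- cand[1L, ]
  flush <- function(cur, merged) {
    merged[[length(merged) + 1L]] <- cur
    merged
  }
  if (nrow(cand) > 1L) {
    for (q in 2:nrow(cand)) {
      nxt <- cand[q, ]
      if (nxt[1L] <= cur[2L]) {               # spike-index overlap
        i <- min(cur[1L], nxt[1L]); j <- max(cur[2L], nxt[2L])
        s_union <- window_surprise(times, i, j, r)
        # merge to the union only when it scores at least as well as
        # either constituent; otherwise keep the better burst
        if (s_union >= max(cur[3L], nxt[3L])) {
          cur <- c(i, j, s_union)
        } else if (nxt[3L] > cur[3L]) {
          cur <- nxt
        }
      } else {
        merged <- flush(cur, merged)
        cur <- nxt
      }
    }
  }
  merged <- flush(cur, merged)
  m <- do.call(rbind, merged)
  out <- data.frame(start_s = times[m[, 1L]], end_s = times[m[, 2L]],
                    n_spikes = as.integer(m[, 2L] - m[, 1L] + 1L),
                    surprise = m[, 3L])
  new_burst_set(out, train)
}

new_burst_set <- function(df, train) {
  structure(df, class = c("burst_set", "data.frame"),
            unit_id = train$unit_id, train = train)
}

#' Burst-load summary of a spike train
#'
#' @param bursts A `burst_set` from [detect_bursts].
#' @param train The `spike_train` the bursts were detected on; defaults
#'   to the train carried by the burst set.
#' @return List with `pct_spikes_in_bursts` (percentage of all spikes
#'   falling inside a burst) and `pct_time_in_bursts` (percentage of the
#'   recording spent inside bursts, with burst duration measured first
#'   to last spike).
#' @export
burst_summary <- function(bursts, train = attr(bursts, "train")) {
  stopifnot(inherits(train, "spike_train"))
  n_total <- length(train$times)
  if (nrow(bursts) == 0L || n_total == 0L) {
    return(list(pct_spikes_in_bursts = 0, pct_time_in_bursts = 0,
                n_bursts = 0L))
  }
  in_burst <- sum(bursts$n_spikes)
  list(pct_spikes_in_bursts = 100 * in_burst / n_total,
       pct_time_in_bursts = 100 * sum(bursts$end_s - bursts$start_s) /
         train$duration,
       n_bursts = nrow(bursts))
}
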