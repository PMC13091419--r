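#' Classify a unit as putative pyramidal neuron or interneuron
#'
#' Region-specific quadrant rule on the (trough-to-peak, rate) plane:
#' interneuron (IN) iff the trough-to-peak time is below the region
#' threshold (0.4 ms in RSC, 0.25 ms in hippocampus) AND the mean rate
#' exceeds 15 Hz; pyramidal (PN) iff the trough-to-peak is at or above
#' the threshold AND the rate is at or below 15 Hz.  Off-quadrant units
#' (narrow+slow or wide+fast) are left unclassified and excluded from
#' PN/IN group statistics.
#'
#' @param features A `unit_features` (or any list with
#'   `trough_to_peak_ms` and `mean_rate_hz`).
#' @param region `"RSC"` or `"HPC"`.
#' @param config An [analysis_config] holding the thresholds.
#' @return One of `"PN"`, `"IN"`, `"unclassified"`.
#' @export
classify_cell_type <- function(features, region = c("RSC", "HPC"),
                               config = analysis_config()) {
  region <- match.arg(region)
  ttp <- features$trough_to_peak_ms
  rate <- features$mean_rate_hz
  thr <- config$in_threshold_ttp_ms[[region]]
  rthr <- config$rate_threshold_hz
  if (is.na(ttp) || is.na(rate)) return("unclassified")
  if (ttp < thr && rate > rthr) return("IN")
  if (ttp >= thr && rate <= rthr) return("PN")
  "unclassified"
}

# Template bin probabilities over ISI histogram breaks (seconds).
# Each template is parameterised from the train itself (mean ISI,
# median ISI), truncated to the binned range and renormalised.
isi_templates <- function(breaks, mean_isi, median_isi) {
  pr <- function(cdf) {
    p <- diff(cdf(breaks))
    p[p < 0] <- 0
    if (sum(p) <= 0) p else p / sum(p)
  }
  list(
    # regular: narrow Gaussian about the mean ISI
    regular = pr(function(x) stats::pnorm(x, mean_isi, mean_isi / 4)),
    # irregular: exponential at the train's mean rate (Poisson ISIs)
    irregular = pr(function(x) stats::pexp(x, 1 / mean_isi)),
    # bursting: early-lag-peaked quasi-normal centred at the median ISI
    # (the intra-burst interval when bursts dominate) over an
    # exponential background carrying the inter-burst gaps
    bursting = pr(function(x) {
      0.75 * stats::pnorm(x, median_isi, median_isi / 2) +
        0.25 * stats::pexp(x, 1 / mean_isi)
    })
  )
}

#' Classify the discharge pattern of a unit
#'
#' Bins the interspike-interval distribution (50 bins up to the 99th
#' ISI percentile) and competes three templates by chi-squared
#' goodness of fit: a symmetric Gaussian about the mean ISI (regular
#' firing), an exponential at the mean rate (irregular / Poisson
#' firing), and an early-peaked quasi-normal (bursting).  Regular
#' splits into `regular_PN` / `regular_IN` by the unit's cell type.
#'
#' @param train A [spike_train] with at least 50 spikes (fewer returns
#'   `"unclassified"`).
#' @param cell_type `"PN"`, `"IN"` or `"unclassified"`, used only to
#'   split the regular class.
#' @param n_bins ISI histogram bins.
#' @return One of `"bursting"`, `"irregular"`, `"regular_PN"`,
#'   `"regular_IN"`, `"unclassified"`.
#' @export
classify_discharge_pattern <- function(train, cell_type = "PN",
                                       n_bins = 50L) {
  stopifnot(inherits(train, "spike_train"))
  if (length(train$times) < 50L) return("unclassified")
  isi <- diff(train$times)
  upper <- stats::quantile(isi, 0.99, names = FALSE)
  upper <- max(upper, max(isi) * 1e-6) * 1.0000001
  if (upper <= 0) return("unclassified")
  breaks <- seq(0, upper, length.out = n_bins + 1L)
  obs <- isi[isi <= upper]
  counts <- graphics::hist(obs, breaks = breaks, plot = FALSE)$counts
  n <- sum(counts)
  tpl <- isi_templates(breaks, mean(isi), stats::median(isi))
  chisq <- vapply(tpl, function(p) {
    e <- n * p
    e <- pmax(e, 0.5)   # guard empty expected cells
    sum((counts - e)^2 / e)
  }, 0)
  cls <- names(tpl)[which.min(chisq)]
  if (cls == "regular") {
    cls <- if (identical(cell_type, "IN")) "regular_IN" else "regular_PN"
  }
  cls
}
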