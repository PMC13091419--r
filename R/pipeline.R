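round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Group-composition table of classified units
#'
#' Per group x region cell: pyramidal (PN) and interneuron (IN) counts
#' with percentages rounded half-up to one decimal, plus grand totals.
#' Unclassified units are excluded from the percentages.
#'
#' @param labels Data frame with columns `group`, `region`,
#'   `cell_type` (`"PN"`, `"IN"` or `"unclassified"`), one row per
#'   unit; or a named numeric layout `list(group.region = c(PN = n,
#'   IN = n), ...)`.
#' @return Data frame with one row per group x region cell: `group`,
#'   `region`, `pn_count`, `pn_pct`, `in_count`, `in_pct`, `empty`
#'   (flag for cells with no classified units, shown as 0.0%), plus a
#'   `totals` attribute with `n_pn`, `n_in`, `n_units`.
#' @export
composition_table <- function(labels) {
  if (is.list(labels) && !is.data.frame(labels)) {
    rows <- lapply(names(labels), function(key) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
      cnt <- labels[[key]]
      data.frame(group = parts[1L], region = parts[2L],
                 cell_type = rep(c("PN", "IN"), c(cnt[["PN"]], cnt[["IN"]])),
                 stringsAsFactors = FALSE)
    })
    labels <- do.call(rbind, rows)
  }
  cells <- split(labels, list(labels$group, labels$region), drop = TRUE)
  out <- lapply(cells, function(d) {
    n_pn <- sum(d$cell_type == "PN")
    n_in <- sum(d$cell_type == "IN")
    tot <- n_pn + n_in
    data.frame(group = d$group[1L], region = d$region[1L],
               pn_count = n_pn,
               pn_pct = if (tot) round_half_up(100 * n_pn / tot) else 0.0,
               in_count = n_in,
               in_pct = if (tot) round_half_up(100 * n_in / tot) else 0.0,
               empty = tot == 0L,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(out, make.row.names = FALSE))
  tab <- tab[order(tab$region, tab$group), ]
  rownames(tab) <- NULL
  attr(tab, "totals") <- c(n_pn = sum(tab$pn_count),
                           n_in = sum(tab$in_count),
                           n_units = sum(tab$pn_count) + sum(tab$in_count))
  tab
}

#' Corrected infarct volume
#'
#' `CIV (%) = [contralateral volume - (ipsilateral volume - infarct
#' volume)] / contralateral volume x 100`: the percentage of the
#' ipsilateral hemisphere lost, corrected for oedema by referencing the
#' contralateral hemisphere.
#'
#' @param contra_vol Contralateral hemisphere volume (> 0).
#' @param ipsi_vol Ipsilateral hemisphere volume (>= 0).
#' @param infarct_vol Infarcted volume, `0 <= infarct_vol <= ipsi_vol`.
#' @return CIV as a percentage.
#' @export
corrected_infarct_volume <- function(contra_vol, ipsi_vol, infarct_vol) {
  if (any(contra_vol <= 0)) stop("contralateral volume must be > 0",
                                 call. = FALSE)
  if (any(infarct_vol < 0) || any(infarct_vol > ipsi_vol)) {
    stop("infarct volume must lie in [0, ipsilateral volume]",
         call. = FALSE)
  }
  (contra_vol - (ipsi_vol - infarct_vol)) / contra_vol * 100
}

#' Run the full cohort analysis pipeline
#'
#' Executes classification, burst detection, pairwise synchrony, LFP
#' band analysis, spike-field coherence and spike-phase statistics over
#' a cohort (simulated via [simulate_cohort] or loaded from
#' [read_spike_table]/[read_continuous] output), in stage order, and
#' aggregates a per-group report.  Deterministic given the
#' configuration seed.
#'
#' @param config An [analysis_config]; its `seed` drives simulation.
#' @param cohort A `cohort` object; when `NULL` one is simulated from
#'   `spec`.
#' @param spec A [cohort_spec] used when `cohort` is `NULL` (its seed
#'   is overridden by `config$seed`).
#' @param out_dir Optional directory; when given, result tables and a
#'   JSON run summary are written via [write_results].
#' @return A `cohort_report`: list of data frames `units` (features,
#'   labels, burst and phase statistics per unit), `composition`,
#'   `group_summary` (per group x region medians), `band_auc`, and the
#'   `config` used.
#' @export
run_pipeline <- function(config = analysis_config(), cohort = NULL,
                         spec = cohort_spec(), out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(cohort)) {
    spec$seed <- as.integer(config$seed)
    cohort <- simulate_cohort(spec)
  }
  if (length(cohort$trains) == 0L) {
    stop("cohort contains no units; nothing to analyse", call. = FALSE)
  }
  bands <- config$bands
  rows <- list()
  for (uid in names(cohort$trains)) {
    tr <- cohort$trains[[uid]]
    key <- paste(tr$group, tr$region, sep = ".")
    lfp <- cohort$lfps[[key]]
    feats <- waveform_features(average_waveform(cohort$waveforms[[uid]]),
                               fs = cohort$waveforms[[uid]]$fs, train = tr)
    ctype <- classify_cell_type(feats, tr$region, config)
    bs <- detect_bursts(tr, surprise_threshold = config$surprise_threshold)
    bsum <- burst_summary(bs, tr)
    ph <- if (length(tr$times) >= 10L) {
      phase_stats(tr, lfp, band = config$coupling_band,
                  n_bins = config$phase_bins_mi)
    } else NULL
    sfc <- if (length(tr$times) >= 10L) {
      suppressMessages(spike_field_coherence(tr, lfp, nfft = config$nfft,
                                             overlap = config$overlap_fraction,
                                             bands = bands))
    } else NULL
    rows[[uid]] <- data.frame(
      unit_id = uid, group = tr$group, region = tr$region,
      n_spikes = length(tr$times), mean_rate_hz = mean_rate(tr),
      trough_to_peak_ms = feats$trough_to_peak_ms,
      half_width_ms = feats$half_width_ms,
      cell_type = ctype,
      n_bursts = bsum$n_bursts,
      pct_spikes_in_bursts = bsum$pct_spikes_in_bursts,
      pct_time_in_bursts = bsum$pct_time_in_bursts,
      plv = if (is.null(ph)) NA_real_ else ph$plv,
      rayleigh_p = if (is.null(ph)) NA_real_ else ph$rayleigh_p,
      mi = if (is.null(ph)) NA_real_ else ph$mi,
      theta_sfc = if (is.null(sfc)) NA_real_ else sfc$band_means[["theta"]],
      alpha_sfc = if (is.null(sfc)) NA_real_ else sfc$band_means[["alpha"]],
      stringsAsFactors = FALSE)
  }
  units <- do.call(rbind, c(rows, make.row.names = FALSE))

  # pairwise R^2 within each group x region (smoothed 12.5 ms rates)
  r2_rows <- list()
  for (key in names(cohort$lfps)) {
    ids <- units$unit_id[paste(units$group, units$region, sep = ".") == key]
    ids <- ids[units$n_spikes[match(ids, units$unit_id)] >= 10L]
    if (length(ids) < 2L) next
    rates <- lapply(cohort$trains[ids], binned_rate,
                    bin_ms = config$rate_bin_ms,
                    smooth_sigma_ms = config$smooth_sigma_ms)
    M <- suppressWarnings(pairwise_r2_matrix(rates))
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    r2_rows[[key]] <- data.frame(group = parts[1L], region = parts[2L],
                                 median_offdiag_r2 =
                                   stats::median(M[upper.tri(M)]),
                                 n_pairs = sum(upper.tri(M)),
                                 stringsAsFactors = FALSE)
  }
  r2_tab <- do.call(rbind, c(r2_rows, make.row.names = FALSE))

  # LFP band areas per group x region
  auc_rows <- lapply(names(cohort$lfps), function(key) {
    ps <- power_spectrum(cohort$lfps[[key]], nfft = config$nfft,
                         overlap = config$overlap_fraction)
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    cbind(data.frame(group = parts[1L], region = parts[2L],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(band_auc(ps, bands))))
  })
  auc_tab <- do.call(rbind, c(auc_rows, make.row.names = FALSE))

  gs <- stats::aggregate(
    units[c("mean_rate_hz", "pct_spikes_in_bursts", "pct_time_in_bursts",
            "plv", "mi", "theta_sfc", "alpha_sfc")],
    by = units[c("group", "region")], FUN = stats::median, na.rm = TRUE)
  if (!is.null(r2_tab)) {
    gs <- merge(gs, r2_tab[c("group", "region", "median_offdiag_r2")],
                by = c("group", "region"), all.x = TRUE)
  }

  report <- structure(list(units = units,
                           composition = composition_table(units),
                           group_summary = gs,
                           band_auc = auc_tab,
                           config = config),
                      class = "cohort_report")
  if (!is.null(out_dir)) {
    write_results(
      list(units = units, composition = report$composition,
           group_summary = gs, band_auc = auc_tab),
      out_dir,
      summary = list(seed = config$seed,
                     parameters = unclass(config)[setdiff(names(config),
                                                          "bands")],
                     bands = config$bands,
                     n_units = nrow(units)))
  }
  report
}
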