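#' Construct a spike train
#'
#' The atom of all spike analyses: the ordered spike times of one sorted
#' single unit, together with its recording region and hemisphere group.
#'
#' @param unit_id Character scalar identifying the unit.
#' @param times Numeric vector of spike times in seconds.  Must lie in
#'   `[0, duration]`.  Duplicate timestamps (refractory violations) are
#'   collapsed to a single spike with a warning.
#' @param duration Recording duration in seconds (> 0).
#' @param region One of `"RSC"` (retrosplenial cortex) or `"HPC"`
#'   (hippocampal CA1).
#' @param group One of `"sham_left"`, `"sham_right"`, `"hi_contra"`,
#'   `"hi_ipsi"`.
#' @return An object of class `spike_train`: a list with elements
#'   `unit_id`, `region`, `group`, `times` (sorted, strictly increasing)
#'   and `duration`.
#' @export
spike_train <- function(unit_id, times, duration,
                        region = c("RSC", "HPC"),
                        group = c("sham_left", "sham_right",
                                  "hi_contra", "hi_ipsi")) {
  region <- match.arg(region)
  group <- match.arg(group)
  stopifnot(is.character(unit_id), length(unit_id) == 1L)
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0) {
    stop("`duration` must be a single positive number", call. = FALSE)
  }
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times))) {
    stop("spike times must be finite", call. = FALSE)
  }
  if (length(times) && (min(times) < 0 || max(times) > duration)) {
    bad <- which(times < 0 | times > duration)[1L]
    stop(sprintf("spike time %g (index %d) outside [0, %g] for unit '%s'",
                 times[bad], bad, duration, unit_id), call. = FALSE)
  }
  times <- sort(times)
  if (anyDuplicated(times)) {
    n0 <- length(times)
    times <- unique(times)
    warning(sprintf("unit '%s': collapsed %d duplicate spike timestamp(s)",
                    unit_id, n0 - length(times)), call. = FALSE)
  }
  structure(list(unit_id = unit_id, region = region, group = group,
                 times = times, duration = duration),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s  %s/%s  %d spikes over %.4g s (%.3g Hz)\n",
              x$unit_id, x$region, x$group, length(x$times), x$duration,
              length(x$times) / x$duration))
  invisible(x)
}

#' Number of spikes and mean rate of a spike train
#' @param train A `spike_train`.
#' @return Mean firing rate in Hz (spike count / duration).
#' @export
mean_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  length(train$times) / train$duration
}

#' Construct an LFP signal
#'
#' A uniformly sampled continuous field trace: the atom of all spectral
#' and phase analyses.
#'
#' @param samples Numeric vector of samples in microvolts.
#' @param fs Sampling rate in Hz (> 0).
#' @inheritParams spike_train
#' @return An object of class `lfp_signal` with elements `samples`, `fs`,
#'   `region`, `group` and `duration` (seconds).
#' @export
lfp_signal <- function(samples, fs, region = c("RSC", "HPC"),
                       group = c("sham_left", "sham_right",
                                 "hi_contra", "hi_ipsi")) {
  region <- match.arg(region)
  group <- match.arg(group)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("zero-length LFP signal", call. = FALSE)
  if (any(!is.finite(samples))) {
    stop(sprintf("non-finite LFP sample at index %d",
                 which(!is.finite(samples))[1L]), call. = FALSE)
  }
  structure(list(samples = samples, fs = fs, region = region, group = group,
                 duration = length(samples) / fs),
            class = "lfp_signal")
}

#' @export
print.lfp_signal <- function(x, ...) {
  cat(sprintf("<lfp_signal> %s/%s  %d samples at %g Hz (%.4g s)\n",
              x$region, x$group, length(x$samples), x$fs, x$duration))
  invisible(x)
}

#' Default analysis configuration
#'
#' Houses every tunable parameter of the pipeline with the recording
#' protocol's defaults: region-specific interneuron trough-to-peak thresholds
#' (RSC 0.4 ms, hippocampus 0.25 ms), the 15 Hz interneuron rate
#' threshold, the Poisson-surprise burst threshold of 5, the five
#' oscillation bands (delta 0-4, theta 4-8, alpha 8-12, beta 12-30,
#' gamma 30-50 Hz), the 4-12 Hz theta-alpha coupling band, Welch
#' parameters (256-point blocks, 5% overlap), the 12.5 ms rate bin, the
#' 600-6000 Hz spike filter with 50 uV threshold and 40-sample window,
#' and 18 phase bins for the modulation index.
#'
#' @param ... Named overrides of any default field.  Unknown names are an
#'   error.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    in_threshold_ttp_ms = c(RSC = 0.4, HPC = 0.25),
    rate_threshold_hz = 15,
    surprise_threshold = 5,
    bands = list(delta = c(0, 4), theta = c(4, 8), alpha = c(8, 12),
                 beta = c(12, 30), gamma = c(30, 50)),
    coupling_band = c(4, 12),
    nfft = 256,
    overlap_fraction = 0.05,
    rate_bin_ms = 12.5,
    smooth_sigma_ms = 25,
    spike_filter_hz = c(600, 6000),
    spike_threshold_uv = 50,
    spike_window_samples = 40,
    spike_align_sample = 10,
    lfp_rate_hz = 500,
    coherence_range_hz = c(0.5, 100),
    phase_bins_mi = 18,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("configuration overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop(sprintf("unknown configuration key(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  edges <- unlist(cfg$bands)
  bm <- matrix(edges, nrow = 2)
  if (any(bm[2, ] <= bm[1, ])) stop("bands must have positive width", call. = FALSE)
  if (ncol(bm) > 1 && any(bm[1, -1] < bm[2, -ncol(bm)])) {
    stop("bands must be non-overlapping and ordered", call. = FALSE)
  }
  if (cfg$overlap_fraction < 0 || cfg$overlap_fraction >= 1) {
    stop("overlap_fraction must be in [0, 1)", call. = FALSE)
  }
  for (key in c("rate_threshold_hz", "surprise_threshold", "nfft",
                "rate_bin_ms", "spike_threshold_uv", "spike_window_samples",
                "phase_bins_mi", "lfp_rate_hz")) {
    if (any(cfg[[key]] <= 0)) stop(sprintf("%s must be > 0", key), call. = FALSE)
  }
  invisible(cfg)
}

#' Read a spike event table
#'
#' Parses a comma-separated event table with header columns `unit_id`,
#' `region`, `group`, `time_s`, `duration_s` into one [spike_train] per
#' unit.  Times are sorted; duplicate timestamps within a unit collapse
#' to one spike with a warning.
#'
#' @param path Path to the CSV file.
#' @return Named list of `spike_train` objects (possibly empty).
#' @export
read_spike_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("unit_id", "region", "group", "time_s", "duration_s")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop(sprintf("spike table missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(tab) == 0L) return(structure(list(), names = character()))
  bad <- which(tab$time_s < 0 | tab$time_s > tab$duration_s)
  if (length(bad)) {
    stop(sprintf("row %d: time_s = %g outside [0, duration_s = %g]",
                 bad[1L], tab$time_s[bad[1L]], tab$duration_s[bad[1L]]),
         call. = FALSE)
  }
  trains <- lapply(split(tab, tab$unit_id), function(d) {
    spike_train(unit_id = as.character(d$unit_id[1L]), times = d$time_s,
                duration = d$duration_s[1L], region = d$region[1L],
                group = d$group[1L])
  })
  trains[unique(as.character(tab$unit_id))]
}

#' Write spike trains to an event table
#'
#' Inverse of [read_spike_table]; the round trip reproduces spike times
#' bit-exactly (times are printed with full double precision).
#'
#' @param trains List of `spike_train` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(trains, path) {
  rows <- lapply(trains, function(tr) {
    if (length(tr$times) == 0L) return(NULL)
    data.frame(unit_id = tr$unit_id, region = tr$region, group = tr$group,
               time_s = sprintf("%.17g", tr$times),
               duration_s = sprintf("%.17g", tr$duration),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(unit_id = character(), region = character(),
                      group = character(), time_s = character(),
                      duration_s = character())
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a continuous signal file
#'
#' Reads either a single-column text file or a raw little-endian 32-bit
#' float stream (extensions `.f32`, `.bin`, `.raw`) into an
#' [lfp_signal].  The sampling rate is not stored in either format and
#' must be supplied.
#'
#' @param path Input file.
#' @param fs Sampling rate in Hz.
#' @param region,group Labels, as in [lfp_signal].
#' @param binary Force binary (`TRUE`) or text (`FALSE`) reading;
#'   default guesses from the file extension.
#' @return An `lfp_signal`; the sample count of the file is preserved
#'   exactly.
#' @export
read_continuous <- function(path, fs, region = "RSC", group = "sham_left",
                            binary = NULL) {
  if (is.null(binary)) {
    binary <- grepl("\\.(f32|bin|raw)$", path, ignore.case = TRUE)
  }
  if (binary) {
    n <- file.size(path)
    if (is.na(n) || n == 0L) stop("zero-length stream: ", path, call. = FALSE)
    x <- readBin(path, what = "numeric", n = n %/% 4L, size = 4L,
                 endian = "little")
  } else {
    x <- scan(path, what = double(), quiet = TRUE)
  }
  if (length(x) == 0L) stop("zero-length stream: ", path, call. = FALSE)
  if (any(!is.finite(x))) {
    stop(sprintf("non-finite sample at index %d in %s",
                 which(!is.finite(x))[1L], path), call. = FALSE)
  }
  lfp_signal(x, fs = fs, region = region, group = group)
}

#' Load an analysis configuration from a key-value file
#'
#' Flat `key = value` text (one pair per line, `#` comments allowed).
#' Absent keys take the defaults of [analysis_config]; unknown keys are
#' rejected by name.  Vector-valued fields are written as
#' comma-separated numbers; `bands` as `name:lo-hi` pairs.
#'
#' @param path Config file path.
#' @return An `analysis_config`.
#' @export
load_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(analysis_config())
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1L]],
                     call. = FALSE)
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  parse_val <- function(key, v) {
    if (key == "bands") {
      parts <- strsplit(strsplit(v, ",")[[1]], ":")
      bands <- lapply(parts, function(p) as.numeric(strsplit(trimws(p[2]), "-")[[1]]))
      names(bands) <- trimws(vapply(parts, `[`, "", 1L))
      return(bands)
    }
    num <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
    if (anyNA(num)) trimws(strsplit(v, ",")[[1]]) else num
  }
  overrides <- Map(parse_val, keys, vals)
  names(overrides) <- keys
  do.call(analysis_config, overrides)
}

#' Write result tables and a machine-readable run summary
#'
#' Each element of `tables` (a data frame) is written as
#' `<name>.csv` under `out_dir`; `summary` (parameters, seed, input
#' digests and anything else needed to re-execute the identical run) is
#' written as `run_summary.json`.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @param summary Named list for the JSON run summary.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(tables, out_dir, summary = list()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  if (file.access(out_dir, 2L) != 0L) {
    stop("output directory not writable: ", out_dir, call. = FALSE)
  }
  files <- character()
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  sf <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, sf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(files, sf))
}
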