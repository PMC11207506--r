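#' Time-series record
#'
#' Container for one uniformly sampled physiological channel. PPG is
#' conventionally sampled at 100 Hz and the reference ECG at 256 Hz.
#'
#' @param samples Numeric vector of sample values (arbitrary units).
#' @param fs Sampling rate in Hz (> 0).
#' @param channel `"PPG"` or `"ECG"`.
#' @param subject_id Subject identifier.
#' @param t0 Start-time offset in seconds.
#' @return An object of class `ts_record`.
#' @export
ts_record <- function(samples, fs, channel = c("PPG", "ECG"),
                      subject_id = "S01", t0 = 0) {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("ts_record: samples must be non-empty")
  if (!is.finite(fs) || fs <= 0) stop("ts_record: fs must be > 0")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("ts_record: samples contain missing or non-finite values")
  structure(list(samples = samples, fs = fs, channel = channel,
                 subject_id = subject_id, t0 = t0),
            class = "ts_record")
}

#' @export
print.ts_record <- function(x, ...) {
  cat(sprintf("<ts_record> %s subject=%s fs=%g Hz n=%d (%.1f s)\n",
              x$channel, x$subject_id, x$fs, length(x$samples),
              length(x$samples) / x$fs))
  invisible(x)
}

#' One fixed-length analysis window of a record
#'
#' @param samples Numeric vector of length `round(fs * window_s)`.
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds (default 10).
#' @param index Zero-based ordinal of the window within its session.
#' @param subject_id Subject identifier.
#' @return An object of class `ppg_segment`.
#' @export
ppg_segment <- function(samples, fs, window_s = 10, index = 0L,
                        subject_id = "S01") {
  expected <- round(fs * window_s)
  if (length(samples) != expected)
    stop(sprintf("ppg_segment: expected %d samples (fs*window_s), got %d",
                 expected, length(samples)))
  structure(list(samples = as.numeric(samples), fs = fs, window_s = window_s,
                 index = as.integer(index), subject_id = subject_id),
            class = "ppg_segment")
}

#' Pipeline run configuration
#'
#' Holds every tunable the pipeline reads, with the published defaults:
#' cardiac detection band 0.83-2.16 Hz, usability threshold 5 BPM
#' (inclusive), reject rate 30 %.
#'
#' @param window_s Segment length in seconds.
#' @param hr_band_hz Length-2 numeric, cardiac band in Hz.
#' @param usability_threshold_bpm Absolute HR error (BPM) at or below which a
#'   segment counts as usable.
#' @param reject_rate Target fraction of segments to discard.
#' @param energy_budget_mJ Per-segment energy budget in millijoules
#'   (`Inf` = unconstrained).
#' @param seed Integer seed recorded with every run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(window_s = 10, hr_band_hz = c(0.83, 2.16),
                       usability_threshold_bpm = 5, reject_rate = 0.30,
                       energy_budget_mJ = Inf, seed = 1L) {
  stopifnot(length(hr_band_hz) == 2, hr_band_hz[1] < hr_band_hz[2],
            reject_rate >= 0, reject_rate < 1, window_s > 0,
            usability_threshold_bpm >= 0)
  structure(list(window_s = window_s, hr_band_hz = hr_band_hz,
                 usability_threshold_bpm = usability_threshold_bpm,
                 reject_rate = reject_rate,
                 energy_budget_mJ = energy_budget_mJ,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from JSON or YAML
#'
#' Any key present in the file overrides the corresponding
#' [run_config()] default; unknown keys are an error.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("load_config: the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("load_config: unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Read a signal file with its metadata sidecar
#'
#' The signal file is delimited text with header `value` or `t,value`, one
#' sample per row. The sidecar is JSON with keys `fs_hz`, `channel`,
#' `subject_id`. Missing values are rejected (no gap filling).
#'
#' @param path Signal CSV path.
#' @param meta Sidecar JSON path; defaults to `<path>.json`.
#' @return A [ts_record()].
#' @export
load_record <- function(path, meta = paste0(path, ".json")) {
  if (!file.exists(meta)) stop("load_record: missing metadata sidecar: ", meta)
  md <- jsonlite::read_json(meta, simplifyVector = TRUE)
  if (is.null(md$fs_hz) || !is.numeric(md$fs_hz) || md$fs_hz <= 0)
    stop("load_record: configuration error: sidecar must declare fs_hz > 0")
  dat <- utils::read.csv(path, colClasses = "character")
  col <- if ("value" %in% names(dat)) dat$value else dat[[ncol(dat)]]
  x <- suppressWarnings(as.numeric(col))
  bad <- which(!is.finite(x))
  if (length(bad))
    stop(sprintf("load_record: parse error: non-numeric value at data row %d ('%s')",
                 bad[1], col[bad[1]]))
  ts_record(x, fs = md$fs_hz,
            channel = if (is.null(md$channel)) "PPG" else md$channel,
            subject_id = if (is.null(md$subject_id)) "S01" else md$subject_id,
            t0 = if (is.null(md$t0)) 0 else md$t0)
}

#' Write a record and its sidecar to disk
#'
#' Values are written with full precision (`format = "%.17g"` via
#' `as.character`), so finite decimal inputs round-trip bit-identically.
#'
#' @param rec A [ts_record()].
#' @param path Output CSV path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_record <- function(rec, path) {
  stopifnot(inherits(rec, "ts_record"))
  con <- file(path, "w")
  writeLines("value", con)
  writeLines(format(rec$samples, digits = 17, trim = TRUE, scientific = FALSE),
             con)
  close(con)
  jsonlite::write_json(
    list(fs_hz = rec$fs, channel = rec$channel, subject_id = rec$subject_id,
         t0 = rec$t0),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Cut a record into non-overlapping fixed-length segments
#'
#' Consecutive, non-overlapping windows; a trailing remainder shorter than
#' one window is dropped.
#'
#' @param rec A [ts_record()].
#' @param window_s Window length in seconds (default 10).
#' @return List of [ppg_segment()]s (possibly empty, with a warning).
#' @export
segment_signal <- function(rec, window_s = 10) {
  stopifnot(inherits(rec, "ts_record"))
  L <- round(rec$fs * window_s)
  k <- length(rec$samples) %/% L
  if (k == 0) {
    warning("segment_signal: record shorter than one window; no segments")
    return(list())
  }
  lapply(seq_len(k) - 1L, function(i) {
    ppg_segment(rec$samples[(i * L + 1):((i + 1) * L)], fs = rec$fs,
                window_s = window_s, index = i, subject_id = rec$subject_id)
  })
}
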