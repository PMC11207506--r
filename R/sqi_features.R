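# The 14 signal-quality indices (SQIs) computed on the RAW segment,
# before any processing: six amplitude statistics, six power-spectral
# quantities, their ratio, and the spectral standard deviation.

SQI_NAMES <- c("median", "range", "std", "kurtosis", "skewness", "entropy",
               "psd_1hz", "psd_3hz", "psd_5hz", "psd_7hz",
               "psd_001_1hz", "psd_1_3hz", "psd_ratio", "std_spectrum")

#' Extract the 14 signal-quality indices from one segment
#'
#' Amplitude statistics use population normalisation; kurtosis is excess
#' (normal -> 0); entropy is the Shannon entropy (natural log) of a 16-bin
#' equal-width amplitude histogram. Spectral quantities come from the
#' mean-removed one-sided periodogram on the un-padded grid (0.1 Hz bins
#' for a 10 s window): point PSDs take the bin nearest 1/3/5/7 Hz; band
#' powers sum bins over half-open intervals `[lo, hi)` (DC excluded), so
#' the 1 Hz bin belongs to the 1-3 Hz band and the two bands partition
#' cleanly; `psd_ratio = psd_1_3hz / psd_001_1hz`; `std_spectrum` is the
#' standard deviation of the magnitude spectrum over all non-DC bins up to
#' Nyquist.
#'
#' A constant segment has no spectral content: `psd_ratio` is then `NaN`
#' and the cascade routes such segments straight to DISCARD.
#'
#' @param seg A [ppg_segment()] or numeric vector.
#' @param fs Sampling rate for bare vectors.
#' @param entropy_bins Histogram bin count (default 16).
#' @return Named numeric vector of length 14 (order = `sqi_names()`).
#' @export
extract_sqi <- function(seg, fs = NULL, entropy_bins = 16L) {
  x <- if (inherits(seg, "ppg_segment")) seg$samples else as.numeric(seg)
  fs <- if (inherits(seg, "ppg_segment")) seg$fs else fs
  if (is.null(fs)) stop("extract_sqi: fs required for bare vectors")
  n <- length(x)
  rng <- max(x) - min(x)
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))           # population
  if (sdev > 0) {
    z <- (x - mu) / sdev
    skew <- mean(z^3)
    kurt <- mean(z^4) - 3
  } else skew <- kurt <- 0
  # amplitude-histogram entropy
  if (rng > 0) {
    bins <- pmin(floor((x - min(x)) / rng * entropy_bins) + 1, entropy_bins)
    p <- tabulate(bins, entropy_bins) / n
    p <- p[p > 0]
    ent <- -sum(p * log(p))
  } else ent <- 0

  pg <- periodogram(x, fs)                 # un-padded grid, DC excluded
  nearest_bin <- function(f0) pg$power[which.min(abs(pg$freq - f0))]
  band_power <- function(lo, hi) sum(pg$power[pg$freq >= lo & pg$freq < hi])
  p001_1 <- band_power(0.01, 1)
  p1_3 <- band_power(1, 3)
  mag <- sqrt(pg$power)

  out <- c(median = stats::median(x), range = rng, std = sdev,
           kurtosis = kurt, skewness = skew, entropy = ent,
           psd_1hz = nearest_bin(1), psd_3hz = nearest_bin(3),
           psd_5hz = nearest_bin(5), psd_7hz = nearest_bin(7),
           psd_001_1hz = p001_1, psd_1_3hz = p1_3,
           psd_ratio = if (p001_1 > 0) p1_3 / p001_1 else NaN,
           std_spectrum = stats::sd(mag))
  out[SQI_NAMES]
}

#' SQI feature-name contract
#' @return Character vector of the 14 column names, in model order.
#' @export
sqi_names <- function() SQI_NAMES

#' Feature matrix for a list of segments
#'
#' @param segs Non-empty list of segments (or numeric vectors with `fs`).
#' @param fs Sampling rate for bare vectors.
#' @return `length(segs) x 14` numeric matrix with `sqi_names()` columns.
#' @export
feature_matrix <- function(segs, fs = NULL) {
  if (!length(segs)) stop("feature_matrix: empty input")
  m <- t(vapply(segs, extract_sqi, numeric(14), fs = fs))
  colnames(m) <- SQI_NAMES
  m
}
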