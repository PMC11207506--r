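# Spectral heart-rate estimation, ECG reference, usability labelling and
# error metrics.

periodogram <- function(x, fs, nfft = NULL) {
  x <- x - mean(x)
  n <- length(x)
  if (is.null(nfft)) nfft <- n
  nfft <- max(nfft, n)
  X <- fft(c(x, numeric(nfft - n)))
  half <- floor(nfft / 2)
  freq <- (1:half) * fs / nfft        # DC excluded
  power <- Mod(X[2:(half + 1)])^2 / (n * nfft)
  list(freq = freq, power = power)
}

#' Estimate heart rate from a PPG segment by spectral peak detection
#'
#' The mean-removed segment is zero-padded to at least `nfft` points
#' (default 8192, i.e. a frequency grid finer than 0.75 BPM at 100 Hz —
#' the raw 10 s grid of 6 BPM would be coarser than the 5 BPM usability
#' threshold) and the periodogram argmax inside the closed cardiac band is
#' returned.
#'
#' @param seg A [ppg_segment()] or numeric vector.
#' @param band Length-2 Hz band searched (default `c(0.83, 2.16)`).
#' @param fs Sampling rate for bare vectors.
#' @param nfft Minimum FFT length.
#' @return List with `bpm`, `peak_freq_hz`, `peak_power`.
#' @export
estimate_hr_ppg <- function(seg, band = c(0.83, 2.16), fs = NULL,
                            nfft = 8192L) {
  x <- if (inherits(seg, "ppg_segment")) seg$samples else as.numeric(seg)
  fs <- if (inherits(seg, "ppg_segment")) seg$fs else fs
  if (is.null(fs)) stop("estimate_hr_ppg: fs required for bare vectors")
  if (length(x) < 2 * fs) stop("estimate_hr_ppg: need at least 2 s of signal")
  if (max(x) - min(x) < .Machine$double.eps * max(1, abs(x[1])) * 8)
    stop("estimate_hr_ppg: degenerate input: constant segment has no spectral peak")
  pg <- periodogram(x, fs, nfft)
  inb <- which(pg$freq >= band[1] & pg$freq <= band[2])
  if (!length(inb)) stop("estimate_hr_ppg: no frequency bins inside band")
  i <- inb[which.max(pg$power[inb])]
  list(bpm = 60 * pg$freq[i], peak_freq_hz = pg$freq[i],
       peak_power = pg$power[i])
}

#' Reference heart rate from an ECG segment
#'
#' Pan-Tompkins-style R-peak detection: 5-22 Hz band-pass, squared
#' derivative, 150 ms moving-window integration, adaptive threshold with a
#' 250 ms refractory period. BPM is 60 over the mean RR interval.
#'
#' @param seg A [ppg_segment()] (ECG samples) or numeric vector.
#' @param fs Sampling rate for bare vectors (ECG default 256 Hz).
#' @return Heart rate in BPM.
#' @export
estimate_hr_ecg <- function(seg, fs = NULL) {
  x <- if (inherits(seg, "ppg_segment")) seg$samples else as.numeric(seg)
  fs <- if (inherits(seg, "ppg_segment")) seg$fs else fs
  if (is.null(fs)) stop("estimate_hr_ecg: fs required for bare vectors")
  peaks <- detect_r_peaks(x, fs)
  if (length(peaks) < 2)
    stop("estimate_hr_ecg: reference unavailable: fewer than 2 R peaks")
  rr <- diff(peaks) / fs
  60 / mean(rr)
}

detect_r_peaks <- function(x, fs) {
  if (max(x) - min(x) < 1e-12) return(integer(0))
  sos <- butter_design(2, c(5, 22), fs, "pass")
  y <- filtfilt_sos(sos, x)
  d <- c(0, diff(y)) * fs
  e <- d^2
  w <- max(1L, round(0.150 * fs))
  # centred moving average with shrinking edge windows (no lost energy at
  # the segment boundaries)
  n_e <- length(e)
  half <- w %/% 2
  cs <- cumsum(c(0, e))
  lo_i <- pmax(seq_len(n_e) - half, 1L)
  hi_i <- pmin(seq_len(n_e) + half, n_e)
  integ <- (cs[hi_i + 1] - cs[lo_i]) / (hi_i - lo_i + 1)
  thr <- 0.35 * max(integ)
  refractory <- round(0.250 * fs)
  above <- integ > thr
  dev <- abs(x - stats::median(x))
  peaks <- integer(0)
  i <- 1L
  n <- length(x)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      # locate R on the raw deviation inside the burst; gate out
      # filter-edge ghosts with no supporting raw amplitude
      seg_idx <- i:j
      pk <- seg_idx[which.max(dev[seg_idx])]
      # amplitude gate against filter-edge ghosts; a maximum on the final
      # sample is the truncated flank of the next window's beat
      if (dev[pk] >= 0.25 * max(dev) && pk < n) peaks <- c(peaks, pk)
      i <- j + refractory
    }
    i <- i + 1L
  }
  peaks
}

#' Binary usability label for one estimate
#'
#' A segment is usable (`1`) when the absolute HR error does not exceed the
#' threshold; the boundary is inclusive.
#'
#' @param est Estimated BPM.
#' @param ref Reference BPM.
#' @param thr Threshold in BPM (default 5).
#' @return List with `value` (0/1) and `abs_error_bpm`.
#' @export
usability_label <- function(est, ref, thr = 5) {
  stopifnot(is.finite(est), is.finite(ref))
  err <- abs(est - ref)
  list(value = as.integer(err <= thr), abs_error_bpm = err)
}

#' Heart-rate error metrics over a segment set
#'
#' @param est Numeric vector of estimated BPM.
#' @param ref Numeric vector of reference BPM (same length).
#' @param mask Logical/0-1 vector marking retained segments (default all).
#' @param thr Usability threshold in BPM.
#' @return List: `accuracy_pct` (share of retained segments within `thr`),
#'   `mae_bpm`, `mae_std_bpm`, `rmse_bpm`, `n_retained`, `n_total`.
#' @export
hr_metrics <- function(est, ref, mask = NULL, thr = 5) {
  stopifnot(length(est) == length(ref))
  if (is.null(mask)) mask <- rep(TRUE, length(est))
  stopifnot(length(mask) == length(est))
  mask <- as.logical(mask)
  err <- abs(est - ref)[mask]
  if (!length(err)) stop("hr_metrics: undefined metrics: no retained segments")
  list(accuracy_pct = 100 * mean(err <= thr),
       mae_bpm = mean(err),
       mae_std_bpm = if (length(err) > 1) stats::sd(err) else 0,
       rmse_bpm = sqrt(mean(err^2)),
       n_retained = sum(mask),
       n_total = length(mask))
}
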