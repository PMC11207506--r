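# Empirical mode decomposition by classic sifting with cubic-spline
# envelopes, plus the detrending operator used as the EMD processing
# algorithm: drop every IMF (and the residue) whose dominant periodogram
# frequency lies below a cutoff.

find_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  # collapse flat runs so plateaus yield one extremum
  nz <- which(s != 0)
  if (length(nz) < 2) return(list(max = integer(0), min = integer(0)))
  ds <- diff(s[nz])
  turn <- nz[which(ds != 0) + 1]
  maxima <- turn[s[turn - 1] > 0]
  minima <- turn[s[turn - 1] < 0]
  list(max = maxima, min = minima)
}

# envelope through extrema with mirrored end conditions
spline_envelope <- function(x, idx) {
  n <- length(x)
  if (length(idx) < 2) return(NULL)
  # mirror two boundary extrema beyond each end to tame end swings
  ti <- c(2 - rev(utils::head(idx, 2)), idx, 2 * n - rev(utils::tail(idx, 2)))
  vi <- c(rev(x[utils::head(idx, 2)]), x[idx], rev(x[utils::tail(idx, 2)]))
  keep <- !duplicated(ti)
  stats::splinefun(ti[keep], vi[keep], method = "natural")(seq_len(n))
}

#' Empirical mode decomposition of a numeric signal
#'
#' Standard sifting: an intrinsic mode function (IMF) is accepted when the
#' normalised squared change between sifts drops below `sd_tol` or
#' `max_sift` iterations are reached; decomposition stops when the residue
#' has fewer than 3 extrema or `max_imf` IMFs were extracted.
#'
#' @param x Numeric vector.
#' @param max_imf Maximum number of IMFs.
#' @param sd_tol Cauchy-type sifting stop tolerance (default 0.2).
#' @param max_sift Sift iterations cap per IMF.
#' @return List with `imfs` (list of numeric vectors) and `residue`.
#' @export
emd_decompose <- function(x, max_imf = 10L, sd_tol = 0.2, max_sift = 50L) {
  residue <- x
  imfs <- list()
  for (k in seq_len(max_imf)) {
    ex <- find_extrema(residue)
    if (length(ex$max) + length(ex$min) < 3) break
    h <- residue
    for (it in seq_len(max_sift)) {
      ex_h <- find_extrema(h)
      upper <- spline_envelope(h, ex_h$max)
      lower <- spline_envelope(h, ex_h$min)
      if (is.null(upper) || is.null(lower)) break
      m <- (upper + lower) / 2
      h_new <- h - m
      sdv <- sum(m^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      if (sdv < sd_tol) break
    }
    imfs[[k]] <- h
    residue <- residue - h
  }
  list(imfs = imfs, residue = residue)
}

dominant_freq <- function(x, fs, nfft = 4096L) {
  x <- x - mean(x)
  if (all(abs(x) < 1e-300)) return(0)
  n <- length(x)
  nfft <- max(nfft, n)
  X <- fft(c(x, numeric(nfft - n)))
  half <- floor(nfft / 2)
  p <- Mod(X[2:(half + 1)])^2
  (which.max(p)) * fs / nfft
}

# EMD detrending operator: keep IMFs whose dominant frequency is at or
# above cutoff_hz; drop the rest plus the residue (slow trend).
emd_filter <- function(x, fs, cutoff_hz = 0.25, direction = c("below", "above")) {
  direction <- match.arg(direction)
  dec <- emd_decompose(x)
  if (length(dec$imfs) == 0) return(x - mean(x))
  out <- numeric(length(x))
  for (imf in dec$imfs) {
    f <- dominant_freq(imf, fs)
    keep <- if (direction == "below") f >= cutoff_hz else f <= cutoff_hz
    if (keep) out <- out + imf
  }
  out
}
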