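# SVD of the time-frequency distribution: short-time Fourier transform
# (2 s Hann window, 75 % overlap), rank-2 truncation of the complex STFT
# matrix, inverse by weighted overlap-add. Keeping only the two leading
# singular components isolates the dominant quasi-periodic structure
# (the pulse) and discards diffuse noise energy.

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

stft_frames <- function(n, win_len, hop) {
  starts <- seq(1, n - win_len + 1, by = hop)
  starts
}

# rank-r truncation of the STFT; returns the re-synthesised signal
svdtfd_filter <- function(x, fs, win_s = 2, overlap = 0.75, rank = 2L) {
  n <- length(x)
  win_len <- round(win_s * fs)
  hop <- max(1L, round(win_len * (1 - overlap)))
  if (n < win_len) stop("svdtfd_filter: segment shorter than the STFT window")
  w <- hann_window(win_len)
  starts <- stft_frames(n, win_len, hop)
  Z <- vapply(starts, function(s) fft(x[s:(s + win_len - 1)] * w),
              complex(win_len))
  sv <- svd(Z)
  r <- min(rank, length(sv$d))
  Zr <- sv$u[, seq_len(r), drop = FALSE] %*%
    (sv$d[seq_len(r)] * Conj(t(sv$v[, seq_len(r), drop = FALSE])))
  # weighted overlap-add with window-energy normalisation
  y <- numeric(n)
  wsum <- numeric(n)
  for (k in seq_along(starts)) {
    s <- starts[k]
    frame <- Re(fft(Zr[, k], inverse = TRUE)) / win_len
    y[s:(s + win_len - 1)] <- y[s:(s + win_len - 1)] + frame * w
    wsum[s:(s + win_len - 1)] <- wsum[s:(s + win_len - 1)] + w^2
  }
  ok <- wsum > 1e-8
  y[ok] <- y[ok] / wsum[ok]
  # samples never covered by a full window (extreme edges) fall back to x
  y[!ok] <- x[!ok]
  y
}
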