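# Singular spectrum analysis. The segment is embedded in a Hankel
# trajectory matrix (window L), decomposed by SVD, and each eigentriple is
# reconstructed by diagonal (Hankel) averaging. The SSA processing operator
# drops eigentriples whose dominant frequency falls below a cutoff, except
# that anything inside the cardiac band is always retained so the 1 Hz rule
# cannot delete heart-rate content between 0.83 and 1 Hz.

# diagonal averaging of the rank-1 matrix d * u v^T, via convolution
hankel_rank1 <- function(u, v, d, counts) {
  # antidiagonal sums of outer(u, v): conv(u, v)
  d * convolve_open(u, v) / counts
}

convolve_open <- function(a, b) {
  na <- length(a); nb <- length(b)
  n <- na + nb - 1
  nf <- stats::nextn(n, 2)
  fa <- fft(c(a, numeric(nf - na)))
  fb <- fft(c(b, numeric(nf - nb)))
  Re(fft(fa * fb, inverse = TRUE))[1:n] / nf
}

#' Singular spectrum analysis decomposition and component filtering
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param L Embedding window length in samples (default 400 = 4 s at
#'   100 Hz; 2 s proved too short to separate sub-1 Hz wander from the
#'   cardiac component on 10 s segments).
#' @param cutoff_hz Components with dominant frequency below this are
#'   removed (default 1).
#' @param keep_band Length-2 Hz band always retained (default the cardiac
#'   band 0.83-2.16 Hz).
#' @param direction `"below"` removes components under the cutoff (default),
#'   `"above"` removes components over it.
#' @return Filtered numeric vector, same length as `x`.
#' @export
ssa_filter <- function(x, fs, L = 400L, cutoff_hz = 1,
                       keep_band = c(0.83, 2.16),
                       direction = c("below", "above")) {
  direction <- match.arg(direction)
  n <- length(x)
  if (L >= n) stop("ssa_filter: embedding window must be < length(x)")
  K <- n - L + 1
  X <- matrix(0, L, K)
  for (i in seq_len(L)) X[i, ] <- x[i:(i + K - 1)]
  sv <- svd(X)
  counts <- pmin(pmin(seq_len(n), rev(seq_len(n))), min(L, K))
  total_e <- sum(sv$d^2)
  out <- numeric(n)
  for (i in seq_along(sv$d)) {
    if (sv$d[i]^2 < 1e-12 * total_e) break  # noise floor: negligible energy
    comp <- hankel_rank1(sv$u[, i], sv$v[, i], sv$d[i], counts)
    f <- dominant_freq(comp, fs)
    in_band <- f >= keep_band[1] && f <= keep_band[2]
    keep <- if (direction == "below") (f >= cutoff_hz || in_band)
            else (f <= cutoff_hz || in_band)
    if (keep) out <- out + comp
  }
  out
}
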