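#' @useDynLib qappg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft splinefun approx median sd runif rnorm rpois
NULL

# Butterworth IIR design in zero-pole-gain form, realised as cascaded
# second-order sections and applied forward-backward (zero phase).
# Analog prototype poles for order n: exp(i*pi*(2k + n - 1)/(2n)), k = 1..n.

butter_prototype <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# Design a digital Butterworth filter.
# type: "low", "high" or "pass"; cutoff_hz: scalar or length-2 (band edges).
# Returns an SOS matrix (k x 6) with the overall gain folded into section 1.
butter_design <- function(order, cutoff_hz, fs, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= fs / 2))
    stop("butter_design: cutoffs must lie in (0, fs/2)")
  fs2 <- 2 * fs
  warp <- function(f) fs2 * tan(pi * f / fs)  # bilinear prewarp
  p0 <- butter_prototype(order)

  if (type == "low") {
    wc <- warp(cutoff_hz[1])
    poles <- wc * p0
    zeros <- complex(0)
    gain <- wc^order
  } else if (type == "high") {
    wc <- warp(cutoff_hz[1])
    poles <- wc / p0
    zeros <- rep(0 + 0i, order)
    gain <- 1
  } else {
    if (length(cutoff_hz) != 2 || cutoff_hz[1] >= cutoff_hz[2])
      stop("butter_design: bandpass needs cutoff_hz = c(lo, hi), lo < hi")
    w1 <- warp(cutoff_hz[1]); w2 <- warp(cutoff_hz[2])
    bw <- w2 - w1; w0sq <- w1 * w2
    poles <- complex(0)
    for (p in p0) {
      bp <- bw * p
      disc <- sqrt(bp^2 - 4 * w0sq)
      poles <- c(poles, (bp + disc) / 2, (bp - disc) / 2)
    }
    zeros <- rep(0 + 0i, order)
    gain <- bw^order
  }

  # bilinear transform s -> z
  zd <- (fs2 + zeros) / (fs2 - zeros)
  pd <- (fs2 + poles) / (fs2 - poles)
  gd <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  # degree balancing: remaining zeros at z = -1
  n_fill <- length(pd) - length(zd)
  zd <- c(zd, rep(-1 + 0i, n_fill))
  zpk2sos(zd, pd, gd)
}

# Pair conjugate poles/zeros into biquads. All digital zeros here sit at
# z = +1 or z = -1, so pairing is by simple allocation; poles closest to the
# unit circle are placed in the last sections to limit intermediate growth.
zpk2sos <- function(z, p, k) {
  tol <- 1e-8
  split_conj <- function(v) {
    pos <- v[Im(v) > tol]
    real <- Re(v[abs(Im(v)) <= tol])
    list(pairs = pos, real = real)
  }
  ps <- split_conj(p)
  pair_list <- list()
  for (pp in ps$pairs) pair_list[[length(pair_list) + 1]] <- c(pp, Conj(pp))
  real_p <- ps$real
  while (length(real_p) >= 2) {
    pair_list[[length(pair_list) + 1]] <- real_p[1:2]
    real_p <- real_p[-(1:2)]
  }
  single_p <- if (length(real_p) == 1) real_p else NULL
  # zeros: counts at +1 and -1 (any analog-real zeros map there exactly)
  n_pos <- sum(abs(z - 1) < 1e-6)
  n_neg <- sum(abs(z + 1) < 1e-6)
  stopifnot(n_pos + n_neg == length(z))

  # order sections by pole radius ascending; gain goes on the first section
  ord <- order(vapply(pair_list, function(q) max(Mod(q)), 0))
  pair_list <- pair_list[ord]

  sect <- list()
  take_zeros <- function(m) {
    zz <- numeric(0)
    while (m > 0) {
      if (n_pos >= n_neg && n_pos > 0) { zz <- c(zz, 1); n_pos <<- n_pos - 1 }
      else if (n_neg > 0) { zz <- c(zz, -1); n_neg <<- n_neg - 1 }
      m <- m - 1
    }
    zz
  }
  for (q in pair_list) {
    a <- Re(poly_from_roots(q))
    zz <- take_zeros(2)
    b <- Re(poly_from_roots(zz))
    if (length(b) < 3) b <- c(b, rep(0, 3 - length(b)))
    sect[[length(sect) + 1]] <- c(b, a)
  }
  if (!is.null(single_p)) {
    a <- c(1, -single_p, 0)
    zz <- take_zeros(1)
    b <- if (length(zz) == 1) c(1, -zz, 0) else c(1, 0, 0)
    sect[[length(sect) + 1]] <- c(b, a)
  }
  sos <- do.call(rbind, sect)
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

poly_from_roots <- function(r) {
  p <- 1
  for (x in r) p <- c(p, 0) - c(0, p * x)
  p
}

# Zero-phase filtering: odd-reflection padding, forward pass, reversed pass.
filtfilt_sos <- function(sos, x) {
  n <- length(x)
  pad <- min(n - 1L, 300L)
  if (pad > 0) {
    head_pad <- 2 * x[1] - x[seq(pad + 1, 2)]
    tail_pad <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xe <- c(head_pad, x, tail_pad)
  } else xe <- x
  y <- sosfilt_cpp(sos, xe)
  y <- rev(sosfilt_cpp(sos, rev(y)))
  y[seq(pad + 1, pad + n)]
}

# Squared magnitude response of the forward-backward filter at freq f (Hz).
sos_response <- function(sos, f, fs) {
  w <- exp(-2i * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * w + sos[s, 3] * w^2
    den <- sos[s, 4] + sos[s, 5] * w + sos[s, 6] * w^2
    h <- h * num / den
  }
  Mod(h)^2
}
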