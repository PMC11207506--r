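# Maximal-overlap discrete wavelet transform (MODWT) with the Daubechies
# db8 filter pair. MODWT works at any signal length (no dyadic restriction)
# and is shift-invariant, which suits fixed 10 s segments.

# db8 scaling filter (16 taps, least-asymmetric ordering not required);
# sum = sqrt(2), unit energy, orthogonal to its even shifts.
DB8_SCALING <- c(
  -1.1747678412477009e-04,  6.7544940645057204e-04,
  -3.9174037337694575e-04, -4.8703529934515941e-03,
   8.7460940474057662e-03,  1.3981027917398399e-02,
  -4.4088253930794734e-02, -1.7369301001807943e-02,
   1.2874742662047883e-01,  4.7248457391322918e-04,
  -2.8401554296154718e-01, -1.5829105256349747e-02,
   5.8535468365420651e-01,  6.7563073629729054e-01,
   3.1287159091430028e-01,  5.4415842243104071e-02)

# quadrature mirror: h_l = (-1)^l g_{L-1-l}
db8_wavelet <- function() {
  g <- DB8_SCALING
  L <- length(g)
  rev(g) * (-1)^(seq_len(L) - 1)
}

# circular filtering with an upsampled (a trous) filter at level j
modwt_conv <- function(x, filt, j) {
  n <- length(x)
  step <- 2^(j - 1)
  y <- numeric(n)
  t0 <- seq_len(n)
  for (l in seq_along(filt)) {
    idx <- ((t0 - 1 - (l - 1) * step) %% n) + 1
    y <- y + filt[l] * x[idx]
  }
  y
}

modwt_conv_adj <- function(x, filt, j) {  # adjoint (for synthesis)
  n <- length(x)
  step <- 2^(j - 1)
  y <- numeric(n)
  t0 <- seq_len(n)
  for (l in seq_along(filt)) {
    idx <- ((t0 - 1 + (l - 1) * step) %% n) + 1
    y <- y + filt[l] * x[idx]
  }
  y
}

# Pyramid analysis: returns details W[[1..J]] and smooth V (all length n).
modwt_db8 <- function(x, J) {
  gt <- DB8_SCALING / sqrt(2)
  ht <- db8_wavelet() / sqrt(2)
  W <- vector("list", J)
  V <- x
  for (j in seq_len(J)) {
    W[[j]] <- modwt_conv(V, ht, j)
    V <- modwt_conv(V, gt, j)
  }
  list(W = W, V = V)
}

imodwt_db8 <- function(dec) {
  gt <- DB8_SCALING / sqrt(2)
  ht <- db8_wavelet() / sqrt(2)
  J <- length(dec$W)
  V <- dec$V
  for (j in rev(seq_len(J)))
    V <- modwt_conv_adj(dec$W[[j]], ht, j) + modwt_conv_adj(V, gt, j)
  V
}

# Wavelet filtering operator (WVL): J-level db8 MODWT; zero the level-J
# smooth (baseline, below ~fs/2^(J+1)) and the level-1 detail (top octave
# noise), reconstruct. With fs = 100 Hz, J = 6: removes < ~0.78 Hz and
# > 25 Hz while keeping the cardiac band intact.
wavelet_filter <- function(x, levels = 6L) {
  dec <- modwt_db8(x, levels)
  dec$V <- numeric(length(x))
  dec$W[[1]] <- numeric(length(x))
  imodwt_db8(dec)
}
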