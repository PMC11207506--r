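#' The candidate processing-algorithm pool
#'
#' Nine algorithms: identity bypass, three zero-phase Butterworth filters,
#' and five decomposition-style methods. Per-segment energy costs (mJ)
#' default to published bench measurements and are configuration, not
#' re-measured:
#' bypass 0, BPF 10.05, LPF 10.28, HPF 14.57, CUB 10.85, WVL 9.73,
#' SVDTFD 333.03, EMD 2268.50, SSA 28767.42.
#'
#' @name algorithm_pool
NULL

ALGORITHM_IDS <- c("BYPASS", "BPF", "LPF", "HPF", "CUB", "WVL",
                   "SVDTFD", "EMD", "SSA")

DEFAULT_ENERGY_MJ <- c(
  BYPASS = 0, BPF = 10.05, LPF = 10.28, HPF = 14.57, CUB = 10.85,
  WVL = 9.73, SVDTFD = 333.03, EMD = 2268.50, SSA = 28767.42)

#' Construct one algorithm specification
#'
#' @param id One of `"BYPASS"`, `"BPF"`, `"LPF"`, `"HPF"`, `"CUB"`,
#'   `"WVL"`, `"SVDTFD"`, `"EMD"`, `"SSA"`.
#' @param energy_mJ Per-segment energy cost; defaults to the published
#'   bench value for `id`.
#' @param params Named list of algorithm parameters overriding defaults.
#' @return An object of class `algorithm_spec`.
#' @export
algorithm_spec <- function(id, energy_mJ = NULL, params = list()) {
  if (!id %in% ALGORITHM_IDS)
    stop("algorithm_spec: unknown algorithm id: ", id)
  if (is.null(energy_mJ)) energy_mJ <- unname(DEFAULT_ENERGY_MJ[id])
  if (energy_mJ < 0) stop("algorithm_spec: energy must be >= 0")
  if (id == "BYPASS" && energy_mJ != 0)
    stop("algorithm_spec: BYPASS energy must be 0")
  category <- if (id == "BYPASS") "bypass"
    else if (id %in% c("BPF", "LPF", "HPF")) "filter" else "decompose"
  defaults <- switch(id,
    BPF = list(order = 5, band_hz = c(0.5, 15)),
    LPF = list(order = 5, cutoff_hz = 2.5),
    HPF = list(order = 5, cutoff_hz = 0.5),
    CUB = list(min_trough_spacing_s = 1 / 2.16),
    WVL = list(levels = 6L),
    SVDTFD = list(win_s = 2, overlap = 0.75, rank = 2L),
    EMD = list(cutoff_hz = 0.25, direction = "below"),
    SSA = list(L = 400L, cutoff_hz = 1, keep_band = c(0.83, 2.16),
               direction = "below"),
    list())
  defaults[names(params)] <- params
  structure(list(id = id, category = category, params = defaults,
                 energy_mJ = energy_mJ),
            class = "algorithm_spec")
}

#' List the default algorithm pool
#'
#' @param energy_overrides Optional named numeric vector (or list) of
#'   per-algorithm energies (mJ) replacing the defaults.
#' @return Named list of nine [algorithm_spec()]s in stable id order.
#' @export
list_pool <- function(energy_overrides = NULL) {
  en <- DEFAULT_ENERGY_MJ
  if (!is.null(energy_overrides)) {
    ov <- unlist(energy_overrides)
    bad <- setdiff(names(ov), ALGORITHM_IDS)
    if (length(bad)) stop("list_pool: unknown algorithm ids: ",
                          paste(bad, collapse = ", "))
    en[names(ov)] <- ov
  }
  stats::setNames(
    lapply(ALGORITHM_IDS, function(id) algorithm_spec(id, en[[id]])),
    ALGORITHM_IDS)
}

# Cubic-spline baseline removal: detect pulse troughs (local minima at
# least min_spacing apart, deepest-first) on a 2.5 Hz low-passed copy so
# burst noise cannot plant false anchors, fit a natural cubic spline
# through the smoothed trough values, subtract. Falls back to mean removal
# when the segment has too few troughs to anchor a spline.
cub_filter <- function(x, fs, min_trough_spacing_s = 1 / 2.16) {
  n <- length(x)
  xs <- filtfilt_sos(butter_design(2, 2.5, fs, "low"), x)
  ex <- find_extrema(xs)
  mins <- ex$min
  if (length(mins) >= 2) {
    spacing <- round(min_trough_spacing_s * fs)
    keep <- integer(0)
    for (i in mins[order(xs[mins])]) {       # deepest first
      if (!length(keep) || all(abs(keep - i) >= spacing)) keep <- c(keep, i)
    }
    mins <- sort(keep)
  }
  if (length(mins) < 3) return(x - mean(x))
  base <- stats::splinefun(mins, xs[mins], method = "natural")(seq_len(n))
  x - base
}

#' Apply a processing algorithm to one segment
#'
#' Output length always equals input length; `BYPASS` returns the input
#' unchanged; the Butterworth filters are applied forward-backward so they
#' are zero-phase and cannot shift the spectral peak.
#'
#' @param seg A [ppg_segment()] or numeric vector.
#' @param spec An [algorithm_spec()] or an algorithm id string.
#' @param fs Sampling rate; only needed when `seg` is a bare vector.
#' @return Same type as `seg`, with processed samples.
#' @export
apply_algorithm <- function(seg, spec, fs = NULL) {
  if (is.character(spec)) spec <- algorithm_spec(spec)
  stopifnot(inherits(spec, "algorithm_spec"))
  is_seg <- inherits(seg, "ppg_segment")
  x <- if (is_seg) seg$samples else as.numeric(seg)
  fs <- if (is_seg) seg$fs else fs
  if (is.null(fs)) stop("apply_algorithm: fs required for bare vectors")
  p <- spec$params
  if (spec$id != "BYPASS" && length(x) < 3 * (if (!is.null(p$order)) 2 * p$order + 1 else 10))
    stop("apply_algorithm: segment too short for ", spec$id)
  y <- switch(spec$id,
    BYPASS = x,
    BPF = filtfilt_sos(butter_design(p$order, p$band_hz, fs, "pass"), x),
    LPF = filtfilt_sos(butter_design(p$order, p$cutoff_hz, fs, "low"), x),
    HPF = filtfilt_sos(butter_design(p$order, p$cutoff_hz, fs, "high"), x),
    CUB = cub_filter(x, fs, p$min_trough_spacing_s),
    WVL = wavelet_filter(x, p$levels),
    SVDTFD = svdtfd_filter(x, fs, p$win_s, p$overlap, p$rank),
    EMD = emd_filter(x, fs, p$cutoff_hz, p$direction),
    SSA = ssa_filter(x, fs, p$L, p$cutoff_hz, p$keep_band, p$direction))
  stopifnot(length(y) == length(x))
  if (is_seg) { seg$samples <- y; seg } else y
}
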