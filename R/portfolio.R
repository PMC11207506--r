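# Outcome vectors, normalised Hamming distance, and greedy energy-budgeted
# portfolio formation.

#' Normalised Hamming distance between two binary vectors
#'
#' Fraction of positions at which `u` and `v` differ. A proper metric on
#' binary vectors of fixed length.
#'
#' @param u,v Equal-length binary (0/1) vectors.
#' @return Number in `[0, 1]`.
#' @export
normalized_hamming <- function(u, v) {
  if (length(u) != length(v) || !length(u))
    stop("normalized_hamming: vectors must have equal nonzero length")
  mean(u != v)
}

#' Per-algorithm usability outcome vectors
#'
#' For every algorithm in the pool, every segment is processed, its HR
#' estimated, and the usability bit (error at most `thr` BPM) recorded.
#' Bit order follows segment order identically across algorithms; segments
#' without a finite reference are dropped from every vector so all vectors
#' stay index-aligned.
#'
#' @param segments List of PPG segments.
#' @param pool Named list of [algorithm_spec()]s.
#' @param reference_bpm Numeric vector of reference HR per segment (NA =
#'   reference unavailable).
#' @param band Cardiac band for HR estimation.
#' @param thr Usability threshold in BPM.
#' @return Named list of 0/1 integer vectors, one per algorithm.
#' @export
outcome_vectors <- function(segments, pool, reference_bpm,
                            band = c(0.83, 2.16), thr = 5) {
  stopifnot(length(segments) == length(reference_bpm))
  keep <- is.finite(reference_bpm)
  segments <- segments[keep]
  reference_bpm <- reference_bpm[keep]
  if (!length(segments))
    stop("outcome_vectors: no segments with an available reference")
  lapply(pool, function(spec) {
    vapply(seq_along(segments), function(i) {
      est <- tryCatch(
        estimate_hr_ppg(apply_algorithm(segments[[i]], spec), band)$bpm,
        error = function(e) NA_real_)
      if (!is.finite(est)) return(0L)
      usability_label(est, reference_bpm[i], thr)$value
    }, integer(1))
  })
}

#' Pairwise normalised Hamming distance matrix of outcome vectors
#'
#' @param vectors Named list of equal-length binary vectors.
#' @return Symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(vectors) {
  ids <- names(vectors)
  k <- length(vectors)
  d <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) for (j in seq_len(k))
    if (i < j) d[i, j] <- d[j, i] <-
        normalized_hamming(vectors[[i]], vectors[[j]])
  d
}

#' Energy model for the mechanism
#'
#' @param per_algorithm_mJ Named numeric vector of per-segment algorithm
#'   energies; defaults to the pool defaults.
#' @param sqa_overhead_mJ Energy of computing the SQIs for one segment
#'   (default 35.536 mJ).
#' @param classifier_overhead_mJ Additional classifier inference energy
#'   (default 0; the published overhead already folds it in).
#' @param budget_mJ Per-segment budget (default `Inf`).
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(per_algorithm_mJ = DEFAULT_ENERGY_MJ,
                         sqa_overhead_mJ = 35.536,
                         classifier_overhead_mJ = 0,
                         budget_mJ = Inf) {
  stopifnot(all(per_algorithm_mJ >= 0), sqa_overhead_mJ >= 0,
            classifier_overhead_mJ >= 0, budget_mJ >= 0)
  structure(list(per_algorithm_mJ = per_algorithm_mJ,
                 sqa_overhead_mJ = sqa_overhead_mJ,
                 classifier_overhead_mJ = classifier_overhead_mJ,
                 budget_mJ = budget_mJ),
            class = "energy_model")
}

#' Drop algorithms that do not fit the energy budget
#'
#' An algorithm is admissible when the quality-assessment overhead plus its
#' per-segment energy fits the budget. When the budget cannot even cover
#' the overhead, the mechanism itself is inadmissible and the sentinel
#' string `"one-for-all"` is returned (the caller falls back to a
#' one-for-all pipeline).
#'
#' @param pool Named list of [algorithm_spec()]s.
#' @param em An [energy_model()] with `budget_mJ` set.
#' @return Subset of `pool`, or the string `"one-for-all"`.
#' @export
filter_by_budget <- function(pool, em) {
  overhead <- em$sqa_overhead_mJ + em$classifier_overhead_mJ
  if (em$budget_mJ < overhead) return("one-for-all")
  keep <- vapply(pool, function(s) overhead + s$energy_mJ <= em$budget_mJ,
                 logical(1))
  pool[keep]
}

#' Smallest budget at which an algorithm becomes admissible
#'
#' @param algorithm_id Algorithm id string.
#' @param em An [energy_model()].
#' @return Budget threshold in mJ (overhead + algorithm energy).
#' @export
admissibility_threshold <- function(algorithm_id, em = energy_model()) {
  if (!algorithm_id %in% names(em$per_algorithm_mJ))
    stop("admissibility_threshold: unknown algorithm id: ", algorithm_id)
  em$sqa_overhead_mJ + em$classifier_overhead_mJ +
    unname(em$per_algorithm_mJ[[algorithm_id]])
}

#' Greedy diversity-driven portfolio formation
#'
#' Starting from mandatory BYPASS, repeatedly add the candidate with the
#' highest mean Hamming distance to the already-selected set, until three
#' algorithms are selected or the admitted pool is exhausted. Ties break
#' toward lower energy, then lexicographic id. The result is ordered by
#' ascending energy (BYPASS first).
#'
#' @param pool Admitted pool (named list of [algorithm_spec()]s) containing
#'   BYPASS.
#' @param dm Distance matrix covering the pool ids.
#' @param size Portfolio size cap (default 3).
#' @return Object of class `portfolio`: list with `specs` (ordered specs),
#'   `ids`, `energies`, `mean_pairwise_distance`.
#' @export
form_portfolio <- function(pool, dm, size = 3L) {
  ids <- names(pool)
  if (!"BYPASS" %in% ids)
    stop("form_portfolio: BYPASS is the mandatory initial algorithm")
  stopifnot(all(ids %in% rownames(dm)))
  energies <- vapply(pool, function(s) s$energy_mJ, 0)
  selected <- "BYPASS"
  while (length(selected) < size) {
    cand <- setdiff(ids, selected)
    if (!length(cand)) break
    avg <- vapply(cand, function(cid) mean(dm[cid, selected]), 0)
    best <- max(avg)
    tied <- cand[avg >= best - 1e-12]
    tied <- tied[order(energies[tied], tied)]
    selected <- c(selected, tied[1])
  }
  ord <- order(energies[selected], selected)
  sel <- selected[ord]
  specs <- pool[sel]
  mpd <- if (length(sel) > 1) {
    pairs <- utils::combn(sel, 2)
    mean(dm[cbind(pairs[1, ], pairs[2, ])])
  } else 0
  structure(list(specs = specs, ids = sel,
                 energies = unname(energies[sel]),
                 mean_pairwise_distance = mpd),
            class = "portfolio")
}

#' @export
print.portfolio <- function(x, ...) {
  cat("<portfolio>", paste(x$ids, collapse = " -> "),
      sprintf("(energies %s mJ; mean pairwise distance %.3f)\n",
              paste(format(x$energies), collapse = "/"),
              x$mean_pairwise_distance))
  invisible(x)
}
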