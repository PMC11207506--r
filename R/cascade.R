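# The quality-aware selection cascade: one boosted binary classifier per
# portfolio algorithm, evaluated cheapest algorithm first with early exit;
# a segment rejected by every stage is discarded.

DISCARD <- "DISCARD"

#' Training configuration for the cascade
#'
#' @param grid Data frame of hyperparameter combinations with columns
#'   `max_depth`, `eta`, `nrounds`. Default: depth \{2,3,4\} x learning
#'   rate \{0.1,0.3\} x \{50,100,200\} trees.
#' @param target_reject_rate Desired discard fraction (default 0.30).
#' @param criterion Grid-search criterion: `"balanced_accuracy"` (default)
#'   or `"accuracy"`, computed on pooled out-of-fold predictions.
#' @param seed Integer seed recorded with the model.
#' @return An object of class `training_config`.
#' @export
training_config <- function(grid = expand.grid(max_depth = c(2L, 3L, 4L),
                                               eta = c(0.1, 0.3),
                                               nrounds = c(50L, 100L, 200L)),
                            target_reject_rate = 0.30,
                            criterion = c("balanced_accuracy", "accuracy"),
                            seed = 1L) {
  criterion <- match.arg(criterion)
  stopifnot(nrow(grid) >= 1,
            all(c("max_depth", "eta", "nrounds") %in% names(grid)),
            target_reject_rate >= 0, target_reject_rate < 1)
  structure(list(grid = grid, target_reject_rate = target_reject_rate,
                 criterion = criterion, seed = as.integer(seed)),
            class = "training_config")
}

#' Per-algorithm usability labels for cascade training
#'
#' For each portfolio algorithm independently (multi-label, not mutually
#' exclusive): label 1 when the HR error after that algorithm's processing
#' is at most `thr` BPM.
#'
#' @param segments List of PPG segments.
#' @param portfolio A [form_portfolio()] result (or named list of specs).
#' @param reference_bpm Reference HR per segment.
#' @param band,thr HR band and usability threshold.
#' @return Named list of 0/1 vectors, one per portfolio algorithm.
#' @export
make_labels <- function(segments, portfolio, reference_bpm,
                        band = c(0.83, 2.16), thr = 5) {
  specs <- if (inherits(portfolio, "portfolio")) portfolio$specs else portfolio
  outcome_vectors(segments, specs, reference_bpm, band, thr)
}

balanced_accuracy <- function(y, pred, threshold = 0.5) {
  yhat <- as.integer(pred >= threshold)
  pos <- y == 1
  tpr <- if (any(pos)) mean(yhat[pos] == 1) else NA_real_
  tnr <- if (any(!pos)) mean(yhat[!pos] == 0) else NA_real_
  mean(c(tpr, tnr), na.rm = TRUE)
}

#' Train one cascade stage with grouped grid search
#'
#' Grid search maximises the configured criterion on pooled out-of-fold
#' predictions under leave-one-subject-out folds (no subject ever appears
#' in both the training and validation side of a fold); the winning
#' configuration is refit on all rows. Fully deterministic for a fixed
#' seed and inputs.
#'
#' @param features n x 14 SQI matrix.
#' @param labels Binary vector (both classes must be present).
#' @param tc A [training_config()].
#' @param groups Subject id per row (defines the folds). A single group
#'   disables cross-validation (the first grid row is used directly).
#' @param algorithm_id Id stored with the classifier.
#' @return An object of class `quality_classifier`: `model`, `threshold`
#'   (0.5), `feature_names`, `algorithm_id`, `cv_score`.
#' @export
train_stage <- function(features, labels, tc = training_config(),
                        groups = NULL, algorithm_id = "BYPASS") {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2)
    stop("train_stage: degenerate training for ", algorithm_id,
         ": labels contain a single class")
  if (is.null(groups)) groups <- rep("g1", length(labels))
  stopifnot(length(groups) == length(labels))
  set.seed(tc$seed)
  folds <- unique(groups)
  scorer <- if (tc$criterion == "balanced_accuracy") balanced_accuracy
            else function(y, p, threshold = 0.5) mean((p >= threshold) == y)

  best <- NULL
  if (length(folds) >= 2) {
    for (g in seq_len(nrow(tc$grid))) {
      cfg <- tc$grid[g, ]
      oof <- rep(NA_real_, length(labels))
      ok <- TRUE
      for (f in folds) {
        tr <- groups != f
        if (length(unique(labels[tr])) < 2) { ok <- FALSE; break }
        m <- gbdt_train(features[tr, , drop = FALSE], labels[tr],
                        nrounds = cfg$nrounds, eta = cfg$eta,
                        max_depth = cfg$max_depth)
        oof[!tr] <- predict(m, features[!tr, , drop = FALSE])
      }
      if (!ok) next
      sc <- scorer(labels, oof)
      if (is.null(best) || sc > best$score + 1e-12)
        best <- list(score = sc, cfg = cfg)
    }
  }
  if (is.null(best))
    best <- list(score = NA_real_, cfg = tc$grid[1, ])
  model <- gbdt_train(features, labels, nrounds = best$cfg$nrounds,
                      eta = best$cfg$eta, max_depth = best$cfg$max_depth)
  structure(list(model = model, threshold = 0.5, margin_offset = 0,
                 feature_names = colnames(features),
                 algorithm_id = algorithm_id, cv_score = best$score,
                 config = as.list(best$cfg)),
            class = "quality_classifier")
}

#' Assemble stages into an energy-ordered cascade
#'
#' Stages are re-sorted so the cheapest algorithm is evaluated first; with
#' early exit this ordering minimises expected energy for any per-stage
#' acceptance rates (adjacent-swap argument).
#'
#' @param stages List of `quality_classifier`s, one per portfolio
#'   algorithm (any order).
#' @param portfolio The [form_portfolio()] result the stages were trained
#'   for.
#' @return An object of class `cascade_model`.
#' @export
assemble_cascade <- function(stages, portfolio) {
  stage_ids <- vapply(stages, function(s) s$algorithm_id, "")
  if (!setequal(stage_ids, portfolio$ids) ||
      length(stage_ids) != length(portfolio$ids))
    stop("assemble_cascade: stages do not match the portfolio algorithms")
  energies <- stats::setNames(portfolio$energies, portfolio$ids)
  ord <- order(energies[stage_ids], stage_ids)
  structure(list(stages = stages[ord], portfolio = portfolio,
                 discard_id = DISCARD),
            class = "cascade_model")
}

#' Select a processing algorithm (or DISCARD) for one SQI vector
#'
#' Stages are evaluated in cascade order; the first stage whose predicted
#' probability reaches its threshold wins (later stages are never
#' evaluated). The comparison is done on the log-odds (margin) scale -
#' `margin >= qlogis(threshold) + offset` - which is exactly the
#' probability rule when the calibration offset is 0 but keeps full
#' resolution for confidently classified segments whose probabilities
#' round to 0 or 1. Non-finite features short-circuit to DISCARD.
#'
#' @param cm A [assemble_cascade()] model.
#' @param sqi Numeric vector of 14 SQIs, or an n x 14 matrix.
#' @return Character algorithm id(s), possibly `"DISCARD"`.
#' @export
cascade_select <- function(cm, sqi) {
  stopifnot(inherits(cm, "cascade_model"))
  single <- !is.matrix(sqi)
  X <- if (single) matrix(sqi, nrow = 1,
                          dimnames = list(NULL,
                                          cm$stages[[1]]$feature_names))
       else sqi
  n <- nrow(X)
  out <- rep(cm$discard_id, n)
  ok <- apply(is.finite(X), 1, all)
  undecided <- ok
  for (st in cm$stages) {
    if (!any(undecided)) break
    idx <- which(undecided)
    m <- predict(st$model, X[idx, , drop = FALSE], type = "margin")
    thr <- stats::qlogis(st$threshold) + st$margin_offset
    hit <- m >= thr
    out[idx[hit]] <- st$algorithm_id
    undecided[idx[hit]] <- FALSE
  }
  if (single) out[1] else out
}

cascade_reject_fraction <- function(cm, features) {
  mean(cascade_select(cm, features) == cm$discard_id)
}

#' Calibrate the cascade's discard fraction
#'
#' All stage acceptance thresholds are tightened or relaxed together by a
#' single shared odds multiplier (an additive offset on the log-odds
#' scale), found by bisection so the DISCARD fraction on the validation
#' features lands within +/- 2 percentage points of the target. One
#' degree of freedom, monotone in the offset.
#'
#' @param cm A `cascade_model`.
#' @param features Validation SQI matrix.
#' @param target Target discard fraction in `[0, 1)`.
#' @param tol Acceptable deviation (default 0.02).
#' @return Recalibrated `cascade_model`.
#' @export
calibrate_reject_rate <- function(cm, features, target = 0.30, tol = 0.02) {
  stopifnot(target >= 0, target < 1, nrow(features) >= 1)
  base_off <- vapply(cm$stages, function(s) s$margin_offset, 0)
  apply_off <- function(d) {
    cm2 <- cm
    for (i in seq_along(cm2$stages))
      cm2$stages[[i]]$margin_offset <- base_off[i] + d
    cm2
  }
  lo <- -200; hi <- 200   # log-odds offset bracket
  f_lo <- cascade_reject_fraction(apply_off(lo), features)
  f_hi <- cascade_reject_fraction(apply_off(hi), features)
  if (target < f_lo - tol || target > f_hi + tol)
    stop("calibrate_reject_rate: calibration failure: target reject rate ",
         "unattainable on this validation set")
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    fm <- cascade_reject_fraction(apply_off(mid), features)
    if (fm < target) lo <- mid else hi <- mid
  }
  fr <- c(cascade_reject_fraction(apply_off(lo), features),
          cascade_reject_fraction(apply_off(hi), features))
  best <- c(lo, hi)[which.min(abs(fr - target))]
  out <- apply_off(best)
  if (abs(cascade_reject_fraction(out, features) - target) > tol)
    stop("calibrate_reject_rate: calibration failure: achieved reject rate ",
         "outside tolerance")
  out
}

#' Expected per-segment processing energy of a cascade order
#'
#' For per-stage acceptance rates `accept` (probability a stage accepts a
#' segment that reaches it) and algorithm energies `energy`, in the given
#' stage order. Discarded segments consume no processing energy.
#'
#' @param energy Numeric vector of stage algorithm energies.
#' @param accept Acceptance rates in `[0, 1]`, same length.
#' @param order Permutation of stage indices (default as given).
#' @return Expected energy (same units as `energy`).
#' @export
cascade_expected_energy <- function(energy, accept, order = seq_along(energy)) {
  stopifnot(length(energy) == length(accept))
  e <- 0; reach <- 1
  for (i in order) {
    e <- e + reach * accept[i] * energy[i]
    reach <- reach * (1 - accept[i])
  }
  e
}
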