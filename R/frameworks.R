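# End-to-end frameworks: one-for-all (OFA), signal-quality-assessment
# gating (SQA) and quality-aware processing (QAP), with per-segment
# energy accounting and the four-group selection analysis.

framework_report <- function(framework, metrics, energy_per_segment_mJ,
                             reject_pct, selection_distribution) {
  structure(list(framework = framework,
                 accuracy_pct = metrics$accuracy_pct,
                 mae_bpm = metrics$mae_bpm,
                 mae_std_bpm = metrics$mae_std_bpm,
                 rmse_bpm = metrics$rmse_bpm,
                 energy_per_segment_mJ = energy_per_segment_mJ,
                 reject_pct = reject_pct,
                 n_retained = metrics$n_retained,
                 n_total = metrics$n_total,
                 selection_distribution = selection_distribution),
            class = "framework_report")
}

#' @export
print.framework_report <- function(x, ...) {
  cat(sprintf("<%s> accuracy %.1f%%  MAE %.2f+/-%.2f BPM  RMSE %.2f BPM  energy %.2f mJ/seg  reject %.1f%%\n",
              x$framework, x$accuracy_pct, x$mae_bpm, x$mae_std_bpm,
              x$rmse_bpm, x$energy_per_segment_mJ, x$reject_pct))
  invisible(x)
}

estimate_all <- function(segments, band) {
  vapply(segments, function(s)
    tryCatch(estimate_hr_ppg(s, band)$bpm, error = function(e) NA_real_), 0)
}

#' One-for-all baseline: a single algorithm for every segment
#'
#' No quality assessment happens, so energy is the bare algorithm energy
#' and nothing is rejected.
#'
#' @param segments List of PPG segments.
#' @param algorithm_id Algorithm applied to all segments.
#' @param references Reference BPM per segment.
#' @param band,thr HR band and usability threshold.
#' @param em An [energy_model()].
#' @return A `framework_report`.
#' @export
run_ofa <- function(segments, algorithm_id, references,
                    band = c(0.83, 2.16), thr = 5, em = energy_model()) {
  spec <- algorithm_spec(algorithm_id,
                         em$per_algorithm_mJ[[algorithm_id]])
  est <- vapply(segments, function(s)
    tryCatch(estimate_hr_ppg(apply_algorithm(s, spec), band)$bpm,
             error = function(e) NA_real_), 0)
  ok <- is.finite(est) & is.finite(references)
  m <- hr_metrics(est[ok], references[ok], thr = thr)
  m$n_total <- length(segments)
  sel <- stats::setNames(1, algorithm_id)
  framework_report(sprintf("OFA(%s)", algorithm_id), m,
                   em$per_algorithm_mJ[[algorithm_id]], 0, sel)
}

#' Quality-gating baseline: discard the worst fraction, process nothing
#'
#' A single boosted quality classifier (trained on bypass-usability
#' labels) scores every segment; the lowest-scoring `reject_rate` fraction
#' is discarded and the rest are estimated on the raw signal. Energy is
#' the SQI overhead only.
#'
#' @param segments List of PPG segments.
#' @param references Reference BPM per segment.
#' @param classifier A `quality_classifier` for BYPASS usability.
#' @param reject_rate Fraction to discard.
#' @param band,thr HR band and usability threshold.
#' @param em An [energy_model()].
#' @return A `framework_report`.
#' @export
run_sqa <- function(segments, references, classifier, reject_rate = 0.30,
                    band = c(0.83, 2.16), thr = 5, em = energy_model()) {
  feats <- feature_matrix(segments)
  score <- rep(-Inf, nrow(feats))
  finite_rows <- apply(is.finite(feats), 1, all)
  if (any(finite_rows))
    score[finite_rows] <- predict(classifier$model,
                                  feats[finite_rows, , drop = FALSE])
  n <- length(segments)
  n_rej <- round(reject_rate * n)
  ord <- order(score)               # lowest quality first
  retained <- rep(TRUE, n)
  if (n_rej > 0) retained[ord[seq_len(n_rej)]] <- FALSE
  est <- estimate_all(segments, band)
  ok <- retained & is.finite(est) & is.finite(references)
  m <- hr_metrics(est[ok], references[ok], thr = thr)
  m$n_total <- n
  m$n_retained <- sum(retained)
  sel <- c(stats::setNames(mean(retained), "BYPASS"))
  framework_report("SQA", m,
                   em$sqa_overhead_mJ + em$classifier_overhead_mJ,
                   100 * mean(!retained), sel)
}

#' Quality-aware processing: per-segment algorithm selection
#'
#' Per segment: extract SQIs, run the cascade, process with the selected
#' algorithm (or discard), estimate HR. Energy per segment is the SQI
#' overhead plus the selected algorithm's energy (overhead only for
#' DISCARD and BYPASS, whose processing energy is zero).
#'
#' @param segments List of PPG segments.
#' @param references Reference BPM per segment.
#' @param cascade A calibrated [assemble_cascade()] model.
#' @param band,thr HR band and usability threshold.
#' @param em An [energy_model()].
#' @return A `framework_report` with a `selections` attribute (the chosen
#'   algorithm id per segment).
#' @export
run_qap <- function(segments, references, cascade, band = c(0.83, 2.16),
                    thr = 5, em = energy_model()) {
  feats <- feature_matrix(segments)
  selections <- cascade_select(cascade, feats)
  n <- length(segments)
  est <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (selections[i] == cascade$discard_id) next
    est[i] <- tryCatch(
      estimate_hr_ppg(apply_algorithm(segments[[i]],
                                      cascade$portfolio$specs[[selections[i]]]),
                      band)$bpm,
      error = function(e) NA_real_)
  }
  retained <- selections != cascade$discard_id
  ok <- retained & is.finite(est) & is.finite(references)
  m <- hr_metrics(est[ok], references[ok], thr = thr)
  m$n_total <- n
  m$n_retained <- sum(retained)
  frac <- vapply(cascade$portfolio$ids, function(id) mean(selections == id), 0)
  energy <- em$sqa_overhead_mJ + em$classifier_overhead_mJ +
    sum(frac * vapply(cascade$portfolio$ids,
                      function(id) em$per_algorithm_mJ[[id]], 0))
  rep_ <- framework_report("QAP", m, energy, 100 * mean(!retained), frac)
  attr(rep_, "selections") <- selections
  rep_
}

#' Four-group analysis of QAP selections
#'
#' Groups segments by the cascade's recommendation (I bypass, II second
#' algorithm, III third algorithm, IV discard) and reports each group's
#' accuracy and MAE *without any processing*, exposing the quality
#' gradient the cascade has learned.
#'
#' @param selections Per-segment algorithm ids from [run_qap()].
#' @param segments List of PPG segments.
#' @param references Reference BPM per segment.
#' @param portfolio The portfolio behind the selections.
#' @param band,thr HR band and usability threshold.
#' @return Data frame with one row per group: `group`, `algorithm_id`,
#'   `n`, `accuracy`, `mae_bpm`, `mae_std_bpm` (NA metrics for empty
#'   groups).
#' @export
group_analysis <- function(selections, segments, references, portfolio,
                           band = c(0.83, 2.16), thr = 5) {
  est <- estimate_all(segments, band)
  group_ids <- c(portfolio$ids, DISCARD)
  labels <- c("I", "II", "III", "IV")[seq_along(group_ids)]
  if (length(group_ids) == 4) labels[4] <- "IV"
  out <- lapply(seq_along(group_ids), function(g) {
    sel <- selections == group_ids[g]
    ok <- sel & is.finite(est) & is.finite(references)
    if (!any(ok))
      return(data.frame(group = labels[g], algorithm_id = group_ids[g],
                        n = sum(sel), accuracy = NA_real_,
                        mae_bpm = NA_real_, mae_std_bpm = NA_real_))
    err <- abs(est - references)[ok]
    data.frame(group = labels[g], algorithm_id = group_ids[g], n = sum(sel),
               accuracy = mean(err <= thr), mae_bpm = mean(err),
               mae_std_bpm = if (sum(ok) > 1) stats::sd(err) else 0)
  })
  do.call(rbind, out)
}

#' Side-by-side framework comparison
#'
#' @param reports List of `framework_report`s (at least 2).
#' @param json_path Optional path; when given, the table is also written
#'   as machine-readable JSON.
#' @return Data frame, one column per framework.
#' @export
compare_frameworks <- function(reports, json_path = NULL) {
  stopifnot(length(reports) >= 2)
  tab <- data.frame(
    metric = c("accuracy_pct", "mae_bpm", "mae_std_bpm", "rmse_bpm",
               "energy_per_segment_mJ", "reject_pct"))
  for (r in reports)
    tab[[r$framework]] <- c(r$accuracy_pct, r$mae_bpm, r$mae_std_bpm,
                            r$rmse_bpm, r$energy_per_segment_mJ,
                            r$reject_pct)
  if (!is.null(json_path)) {
    payload <- lapply(reports, function(r)
      r[c("framework", "accuracy_pct", "mae_bpm", "mae_std_bpm", "rmse_bpm",
          "energy_per_segment_mJ", "reject_pct", "n_retained", "n_total",
          "selection_distribution")])
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  tab
}

#' Run the full quality-aware experiment on a synthetic corpus
#'
#' Convenience driver used by the worked example, the acceptance tests and
#' the CLI: generates a corpus, extracts features and labels, forms the
#' portfolio from the admitted pool, trains and calibrates the cascade
#' under leave-one-subject-out hygiene, and runs the OFA / SQA / QAP
#' comparison.
#'
#' @param seed Master seed.
#' @param n_subjects Number of synthetic subjects.
#' @param ps A [protocol_spec()].
#' @param cfg A [run_config()].
#' @param em An [energy_model()].
#' @param tc A [training_config()].
#' @param portfolio_ids Optional fixed portfolio (default: the
#'   budget-filtered greedy portfolio; with the default budget this is
#'   formed from outcome vectors of the cheap half of the pool unless
#'   `full_pool = TRUE`).
#' @param ofa_ids One-for-all baselines to run.
#' @param full_pool Compute outcome vectors for all nine algorithms
#'   (slower; default uses the sub-100 mJ admissible set).
#' @param calibrate_tol Acceptable deviation of the discard fraction from
#'   the target (default 0.02; small corpora may need a looser value
#'   because boosted-tree scores are piecewise constant).
#' @return List: `reports`, `comparison`, `groups`, `portfolio`,
#'   `cascade`, `corpus_truth`, `reject_pct`.
#' @export
run_experiment <- function(seed = 1L, n_subjects = 12L,
                           ps = protocol_spec(), cfg = run_config(seed = seed),
                           em = energy_model(budget_mJ = 100),
                           tc = training_config(seed = seed),
                           portfolio_ids = NULL,
                           ofa_ids = c("BYPASS", "WVL", "SSA"),
                           full_pool = FALSE, calibrate_tol = 0.02) {
  sessions <- generate_corpus(n_subjects, ps, seed = seed,
                              window_s = cfg$window_s)
  corp <- corpus_segments(sessions, cfg$window_s, reference = "ecg")
  keep <- is.finite(corp$reference_bpm)   # segments with a usable reference
  segments <- corp$segments[keep]
  refs <- corp$reference_bpm[keep]
  subjects <- corp$truth$subject_id[keep]
  corp$truth <- corp$truth[keep, ]
  band <- cfg$hr_band_hz
  thr <- cfg$usability_threshold_bpm

  if (is.null(portfolio_ids)) {
    pool <- list_pool(em$per_algorithm_mJ)
    admitted <- filter_by_budget(pool, em)
    if (identical(admitted, "one-for-all"))
      stop("run_experiment: budget below the mechanism overhead; use OFA")
    if (!full_pool)
      admitted <- admitted[names(admitted) %in%
                             c("BYPASS", "BPF", "LPF", "HPF", "CUB", "WVL")]
    ov <- outcome_vectors(segments, admitted, refs, band, thr)
    dm <- distance_matrix(ov)
    pf <- form_portfolio(admitted, dm)
    labels_cache <- ov[pf$ids]
  } else {
    labels_cache <- NULL
    pool <- list_pool(em$per_algorithm_mJ)
    specs <- pool[portfolio_ids]
    energies <- vapply(specs, function(s) s$energy_mJ, 0)
    ord <- order(energies, portfolio_ids)
    pf <- structure(list(specs = specs[ord], ids = portfolio_ids[ord],
                         energies = unname(energies[ord]),
                         mean_pairwise_distance = NA_real_),
                    class = "portfolio")
  }

  feats <- feature_matrix(segments)
  labels <- if (!is.null(labels_cache)) labels_cache
            else make_labels(segments, pf, refs, band, thr)
  stages <- lapply(pf$ids, function(id)
    train_stage(feats, labels[[id]], tc, groups = subjects,
                algorithm_id = id))
  cascade <- assemble_cascade(stages, pf)
  finite_rows <- apply(is.finite(feats), 1, all)
  cascade <- calibrate_reject_rate(cascade, feats[finite_rows, , drop = FALSE],
                                   target = cfg$reject_rate,
                                   tol = calibrate_tol)

  sqa_clf <- stages[[match("BYPASS", pf$ids)]]
  reports <- c(
    lapply(ofa_ids, function(id) run_ofa(segments, id, refs, band, thr, em)),
    list(run_sqa(segments, refs, sqa_clf, cfg$reject_rate, band, thr, em)),
    list(run_qap(segments, refs, cascade, band, thr, em)))
  names(reports) <- c(sprintf("OFA(%s)", ofa_ids), "SQA", "QAP")
  qap <- reports$QAP
  groups <- group_analysis(attr(qap, "selections"), segments, refs, pf,
                           band, thr)
  list(reports = reports, comparison = compare_frameworks(reports),
       groups = groups, portfolio = pf, cascade = cascade,
       corpus_truth = corp$truth, reject_pct = qap$reject_pct)
}
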