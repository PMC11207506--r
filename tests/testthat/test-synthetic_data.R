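test_that("the protocol spec reproduces the session timing", {
  ps <- protocol_spec()
  expect_equal(ps$total_s, 900)                      # 15 min
  expect_equal(ps$repetitions * (ps$static_s + ps$typing_s), ps$total_s)
  tw <- qappg:::typing_windows(ps)
  expect_equal(nrow(tw), 5)
  expect_equal(tw[1, ], c(start = 120, end = 180))
})

test_that("heart-rate traces are seeded, smooth and bounded", {
  sp0 <- subject_params(base_hr_bpm = 70, hr_walk_std = 0, seed = 3)
  tr0 <- generate_hr_trace(sp0, 300)
  expect_true(all(abs(tr0$bpm - 70) < 1e-9))
  sp <- subject_params(base_hr_bpm = 70, hr_walk_std = 2, seed = 3)
  expect_identical(generate_hr_trace(sp, 300)$bpm,
                   generate_hr_trace(sp, 300)$bpm)
  # reflection keeps a long walk within [52, 128]
  big <- generate_hr_trace(subject_params(hr_walk_std = 5, seed = 5), 1e5)
  expect_gte(min(big$bpm), 52)
  expect_lte(max(big$bpm), 128)
})

test_that("clean sessions are recovered within 2 BPM on every segment", {
  sp <- subject_params(artifact_severity = 0, wander_amp = 0,
                       noise_std = 0, seed = 11)
  s <- generate_session(sp)
  segs <- segment_signal(s$ppg)
  est <- vapply(segs, function(g) estimate_hr_ppg(g)$bpm, 0)
  expect_true(all(abs(est - s$truth$true_bpm) < 2))
})

test_that("ECG reference and generator truth agree within 1 BPM", {
  sp <- subject_params(artifact_severity = 1, seed = 12)
  s <- generate_session(sp)
  esegs <- segment_signal(s$ecg)
  bpm <- vapply(esegs, estimate_hr_ecg, 0)
  expect_gte(mean(abs(bpm - s$truth$true_bpm) <= 1), 0.99)
  # constant 60 BPM -> 10 R peaks per 10 s segment
  spc <- subject_params(base_hr_bpm = 60, hr_walk_std = 0,
                        artifact_severity = 0, seed = 1)
  tr <- generate_hr_trace(spc, 900)
  ecg <- generate_ecg(tr, seed = 1)
  seg1 <- segment_signal(ecg)[[2]]
  expect_equal(length(qappg:::detect_r_peaks(seg1$samples, 256)), 10)
})

test_that("sessions and corpora are deterministic given seeds", {
  sp <- subject_params(artifact_severity = 2, seed = 7)
  expect_identical(generate_session(sp)$ppg$samples,
                   generate_session(sp)$ppg$samples)
  ps <- protocol_spec(repetitions = 1L)
  c1 <- generate_corpus(2, ps, seed = 9)
  c2 <- generate_corpus(2, ps, seed = 9)
  expect_identical(c1$S01$ppg$samples, c2$S01$ppg$samples)
  expect_identical(c1$S02$ecg$samples, c2$S02$ecg$samples)
})

test_that("the corpus has the protocol's segment counts and regime flags", {
  corp <- default_corpus()
  expect_length(corp$segments, 12 * 90)              # 12 x 15 min / 10 s
  per_subject <- table(corp$truth$subject_id, corp$truth$regime)
  expect_true(all(per_subject[, "static"] == 60))
  expect_true(all(per_subject[, "typing"] == 30))
})

test_that("artifacts are confined to typing windows", {
  sp <- subject_params(artifact_severity = 6, seed = 13)
  tr <- generate_hr_trace(sp, 900)
  pg <- generate_ppg(tr, sp)
  ps <- protocol_spec()
  t <- (seq_along(pg$artifact) - 1) / 100
  # outside typing windows (with 10 s spill margin) the artifact is zero
  spill <- qappg:::in_typing(t, ps) | qappg:::in_typing(t - 10, ps)
  expect_true(all(pg$artifact[!spill] == 0))
  # a clean subject's static segments are identical across severities
  sp0 <- subject_params(artifact_severity = 0, seed = 13)
  pg0 <- generate_ppg(tr, sp0)
  static_idx <- which(!spill)
  expect_identical(pg$record$samples[static_idx], pg0$record$samples[static_idx])
})

test_that("high severity breaks the bypass path on most typing segments", {
  sp <- subject_params(artifact_severity = 8, seed = 1)
  s <- generate_session(sp)
  segs <- segment_signal(s$ppg)
  typ <- which(s$truth$regime == "typing")
  est <- vapply(typ, function(i)
    tryCatch(estimate_hr_ppg(segs[[i]])$bpm, error = function(e) NA_real_), 0)
  viol <- mean(abs(est - s$truth$true_bpm[typ]) > 5, na.rm = TRUE)
  expect_gte(viol, 0.5)
})

test_that("bypass degradation is monotone in artifact severity", {
  # severity grid, 2 sessions (60 typing segments) per point; Spearman
  # rank correlation of mean |error| with severity
  grid <- c(0.5, 1, 2, 4, 8)
  mae <- vapply(grid, function(sv) {
    errs <- unlist(lapply(1:2, function(k) {
      sp <- subject_params(artifact_severity = sv, seed = 100 + k)
      s <- generate_session(sp)
      segs <- segment_signal(s$ppg)
      typ <- which(s$truth$regime == "typing")
      est <- vapply(typ, function(i)
        tryCatch(estimate_hr_ppg(segs[[i]])$bpm,
                 error = function(e) NA_real_), 0)
      abs(est - s$truth$true_bpm[typ])
    }))
    mean(errs, na.rm = TRUE)
  }, 0)
  expect_gt(cor(mae, grid, method = "spearman"), 0.9)
})

test_that("the corpus plants a processability gradient the cascade can learn", {
  corp <- default_corpus()
  sev <- corpus_severities()
  mid_subjects <- sprintf("S%02d", which(sev >= 1.5 & sev <= 6))
  idx <- which(corp$truth$subject_id %in% mid_subjects &
                 corp$truth$regime == "typing")
  r_by <- rescue_rate(corp, idx, "BYPASS")
  r_bpf <- rescue_rate(corp, idx, "BPF")
  r_cub <- rescue_rate(corp, idx, "CUB")
  r_ssa <- rescue_rate(corp, idx, "SSA")
  r_emd <- rescue_rate(corp, idx, "EMD")
  # mid severities: the cheap filters rescue strictly more than bypass
  expect_gt(r_bpf, r_by)
  expect_gt(r_cub, r_by)
  # the decomposition family rescues at least as much as BPF
  expect_gte(r_ssa, r_bpf)
  expect_gte(max(r_ssa, r_emd), r_bpf)
})
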