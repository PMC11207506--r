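test_that("training config validates its grid and defaults", {
  tc <- training_config()
  expect_equal(nrow(tc$grid), 18)       # 3 depths x 2 rates x 3 sizes
  expect_equal(tc$target_reject_rate, 0.30)
  expect_error(training_config(grid = data.frame()), "grid")
  expect_error(training_config(target_reject_rate = 1))
})

test_that("stage training recovers a planted separable rule", {
  pf <- planted_features()
  tc <- training_config(seed = 1)        # full default grid on tiny data
  st <- train_stage(pf$X, pf$y, tc, groups = pf$groups,
                    algorithm_id = "BYPASS")
  expect_s3_class(st, "quality_classifier")
  expect_gte(st$cv_score, 0.95)          # held-out balanced accuracy
  # determinism: same seed, same data -> identical predictions
  st2 <- train_stage(pf$X, pf$y, tc, groups = pf$groups,
                     algorithm_id = "BYPASS")
  expect_identical(predict(st$model, pf$X), predict(st2$model, pf$X))
  expect_error(train_stage(pf$X, rep(1, nrow(pf$X)), tc),
               "single class")
})

test_that("LOSO hygiene: no subject is in both sides of any fold", {
  pf <- planted_features(n = 80)
  # structural assertion on the fold construction used by train_stage
  folds <- unique(pf$groups)
  for (f in folds) {
    tr <- pf$groups != f
    expect_false(any(pf$groups[tr] == f))
    expect_true(all(pf$groups[!tr] == f))
  }
  expect_gte(length(folds), 2)
})

test_that("cascade assembly reorders stages by ascending algorithm energy", {
  pf <- planted_features()
  tc <- fast_tc()
  mk <- function(id) train_stage(pf$X, pf$y, tc, groups = pf$groups,
                                 algorithm_id = id)
  port <- structure(
    list(specs = list_pool()[c("BYPASS", "BPF", "CUB")],
         ids = c("BYPASS", "BPF", "CUB"),
         energies = c(0, 10.05, 10.85),
         mean_pairwise_distance = NA_real_),
    class = "portfolio")
  stages <- list(mk("CUB"), mk("BPF"), mk("BYPASS"))   # scrambled
  cm <- assemble_cascade(stages, port)
  expect_identical(vapply(cm$stages, `[[`, "", "algorithm_id"),
                   c("BYPASS", "BPF", "CUB"))
  cm2 <- assemble_cascade(cm$stages, port)             # already ordered
  expect_identical(vapply(cm2$stages, `[[`, "", "algorithm_id"),
                   c("BYPASS", "BPF", "CUB"))
  expect_error(assemble_cascade(stages[1:2], port), "do not match")
})

test_that("energy-ascending stage order dominates every permutation", {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  set.seed(55)
  for (rep in 1:300) {
    energy <- sort(runif(3, 0, 100))     # ascending
    accept <- runif(3)
    e_asc <- cascade_expected_energy(energy, accept)
    for (p in perms)
      expect_lte(e_asc, cascade_expected_energy(energy, accept, p) + 1e-12)
  }
})

test_that("selection early-exits, discards on all-reject and is pure", {
  pf <- planted_features()
  tc <- fast_tc()
  st <- train_stage(pf$X, pf$y, tc, groups = pf$groups,
                    algorithm_id = "BYPASS")
  port <- structure(list(specs = list_pool()["BYPASS"], ids = "BYPASS",
                         energies = 0, mean_pairwise_distance = NA_real_),
                    class = "portfolio")
  cm <- assemble_cascade(list(st), port)
  good <- pf$X[which(pf$y == 1)[1], ]
  bad <- pf$X[which(pf$y == 0)[1], ]
  expect_identical(cascade_select(cm, good), "BYPASS")
  expect_identical(cascade_select(cm, bad), "DISCARD")
  # purity: repeated calls identical
  expect_identical(cascade_select(cm, good), cascade_select(cm, good))
  # sentinel features go straight to DISCARD
  nan_row <- good; nan_row[3] <- NaN
  expect_identical(cascade_select(cm, nan_row), "DISCARD")
  # matrix input matches row-wise scalar calls
  M <- rbind(good, bad, nan_row)
  expect_identical(cascade_select(cm, M),
                   c("BYPASS", "DISCARD", "DISCARD"))
})

test_that("reject-rate calibration hits its target by bisection", {
  # graded quality: P(usable) rises smoothly with the std feature, so the
  # fitted margins vary continuously (a separable rule would collapse them
  # into two tied clusters and block intermediate targets)
  set.seed(8)
  n <- 600
  X <- matrix(rnorm(n * 14), n, 14, dimnames = list(NULL, sqi_names()))
  X[, "std"] <- runif(n, 0, 2)
  y <- rbinom(n, 1, plogis(3 * (1 - X[, "std"])))
  groups <- rep(sprintf("g%d", 1:8), length.out = n)
  tc <- fast_tc()
  st <- train_stage(X, y, tc, groups = groups, algorithm_id = "BYPASS")
  pf <- list(X = X)
  port <- structure(list(specs = list_pool()["BYPASS"], ids = "BYPASS",
                         energies = 0, mean_pairwise_distance = NA_real_),
                    class = "portfolio")
  cm <- assemble_cascade(list(st), port)
  for (target in c(0.05, 0.30, 0.60)) {
    cal <- calibrate_reject_rate(cm, pf$X, target = target)
    achieved <- mean(cascade_select(cal, pf$X) == "DISCARD")
    expect_lte(abs(achieved - target), 0.02)
  }
  # constant features -> constant score -> most targets unattainable
  const <- matrix(1, 50, 14, dimnames = list(NULL, sqi_names()))
  expect_error(calibrate_reject_rate(cm, const, target = 0.5),
               "calibration failure")
})

test_that("labels for BYPASS equal its outcome-vector bits", {
  segs <- lapply(c(60, 80, 100), function(b)
    ppg_segment(pulse_wave(b), fs = 100))
  refs <- c(60, 80, 100)
  pool <- list_pool()["BYPASS"]
  expect_identical(make_labels(segs, pool, refs)$BYPASS,
                   outcome_vectors(segs, pool, refs)$BYPASS)
})
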