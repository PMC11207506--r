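test_that("normalized hamming distance matches its worked examples", {
  u <- c(1, 0, 1, 1, 0, 0, 1, 0)
  v <- u; v[3] <- 0
  expect_identical(normalized_hamming(u, v), 1 / 8)
  expect_identical(normalized_hamming(u, u), 0)
  expect_identical(normalized_hamming(u, 1 - u), 1)
  expect_error(normalized_hamming(u, v[-1]), "equal nonzero length")
})

test_that("normalized hamming satisfies the metric axioms", {
  set.seed(21)
  for (n in 2:10) {
    for (rep in 1:40) {
      a <- sample(0:1, n, replace = TRUE)
      b <- sample(0:1, n, replace = TRUE)
      c <- sample(0:1, n, replace = TRUE)
      expect_identical(normalized_hamming(a, a), 0)
      expect_identical(normalized_hamming(a, b), normalized_hamming(b, a))
      expect_gte(normalized_hamming(a, c) + normalized_hamming(c, b),
                 normalized_hamming(a, b) - 1e-15)
      if (any(a != b)) expect_gt(normalized_hamming(a, b), 0)
    }
  }
})

test_that("budget filtering reproduces the worked admissibility examples", {
  pool <- list_pool()
  em100 <- energy_model(budget_mJ = 100)
  adm <- filter_by_budget(pool, em100)
  expect_setequal(names(adm), c("BYPASS", "WVL", "BPF", "LPF", "CUB", "HPF"))
  expect_identical(filter_by_budget(pool, energy_model(budget_mJ = 30)),
                   "one-for-all")
  expect_length(filter_by_budget(pool, energy_model(budget_mJ = Inf)), 9)
})

test_that("admissibility thresholds equal overhead plus algorithm energy", {
  expect_equal(admissibility_threshold("SVDTFD"), 35.536 + 333.03)
  expect_equal(admissibility_threshold("SSA"), 35.536 + 28767.42)
  expect_equal(admissibility_threshold("BYPASS"), 35.536)
  expect_error(admissibility_threshold("NOPE"), "unknown algorithm")
  # threshold is exactly the smallest admitting budget
  pool <- list_pool()
  thr <- admissibility_threshold("SVDTFD")
  expect_true("SVDTFD" %in%
                names(filter_by_budget(pool, energy_model(budget_mJ = thr))))
  expect_false("SVDTFD" %in%
                 names(filter_by_budget(pool,
                                        energy_model(budget_mJ = thr - 0.01))))
})

test_that("greedy portfolio formation follows the documented trace", {
  pool <- list_pool()[c("BYPASS", "BPF", "CUB")]   # stand-ins for A, B
  dm <- matrix(0, 3, 3, dimnames = list(c("BYPASS", "BPF", "CUB"),
                                        c("BYPASS", "BPF", "CUB")))
  dm["BYPASS", "BPF"] <- dm["BPF", "BYPASS"] <- 0.3   # A = BPF
  dm["BYPASS", "CUB"] <- dm["CUB", "BYPASS"] <- 0.2   # B = CUB
  dm["BPF", "CUB"] <- dm["CUB", "BPF"] <- 0.1
  pf <- form_portfolio(pool, dm)
  expect_identical(pf$ids, c("BYPASS", "BPF", "CUB"))  # ascending energy
  expect_equal(pf$mean_pairwise_distance, mean(c(0.3, 0.2, 0.1)))

  pf2 <- form_portfolio(list_pool()[c("BYPASS", "BPF")],
                        dm[1:2, 1:2])
  expect_length(pf2$ids, 2)
  expect_error(form_portfolio(list_pool()["BPF"], dm), "BYPASS")
})

test_that("greedy formation equals a brute-force trace on random pools", {
  # independent oracle: literal re-implementation of the greedy rule
  brute_greedy <- function(ids, energies, dm, size = 3) {
    sel <- "BYPASS"
    while (length(sel) < size) {
      cand <- setdiff(ids, sel)
      if (!length(cand)) break
      avg <- sapply(cand, function(cc) mean(dm[cc, sel]))
      mx <- max(avg)
      tied <- cand[avg >= mx - 1e-12]
      tied <- tied[order(energies[tied], tied)]
      sel <- c(sel, tied[1])
    }
    sel[order(energies[sel], sel)]
  }
  set.seed(33)
  all_ids <- names(list_pool())
  for (rep in 1:200) {
    k <- sample(2:6, 1)
    ids <- c("BYPASS", sample(setdiff(all_ids, "BYPASS"), k - 1))
    pool <- list_pool()[ids]
    d <- matrix(0, k, k, dimnames = list(ids, ids))
    vals <- runif(k * (k - 1) / 2)
    d[lower.tri(d)] <- vals
    d <- d + t(d)
    en <- vapply(pool, function(s) s$energy_mJ, 0)
    expect_identical(form_portfolio(pool, d)$ids, brute_greedy(ids, en, d))
  }
})

test_that("greedy portfolios are at least as diverse as the worst random pick", {
  set.seed(44)
  ids <- names(list_pool())[1:6]
  pool <- list_pool()[ids]
  wins <- 0; total <- 100
  for (rep in seq_len(total)) {
    d <- matrix(0, 6, 6, dimnames = list(ids, ids))
    d[lower.tri(d)] <- runif(15)
    d <- d + t(d)
    pf <- form_portfolio(pool, d)
    mpd <- function(sel) {
      pr <- utils::combn(sel, 2); mean(d[cbind(pr[1, ], pr[2, ])])
    }
    others <- utils::combn(setdiff(ids, "BYPASS"), 2)
    worst <- min(apply(others, 2, function(p) mpd(c("BYPASS", p))))
    if (pf$mean_pairwise_distance >= worst - 1e-12) wins <- wins + 1
  }
  expect_gte(wins / total, 0.95)
})

test_that("outcome vectors align with segments and flag clean corpora usable", {
  segs <- lapply(c(60, 75, 90, 110), function(b)
    ppg_segment(pulse_wave(b), fs = 100))
  refs <- c(60, 75, 90, 110)
  ov <- outcome_vectors(segs, list_pool()[c("BYPASS", "BPF")], refs)
  expect_named(ov, c("BYPASS", "BPF"))
  expect_identical(ov$BYPASS, rep(1L, 4))           # clean by construction
  expect_length(ov$BPF, 4)
  # identical processing -> distance 0
  ov2 <- outcome_vectors(segs, list(X = algorithm_spec("BYPASS"),
                                    Y = algorithm_spec("BYPASS")), refs)
  expect_identical(normalized_hamming(ov2$X, ov2$Y), 0)
  # unavailable references drop segments from every vector, aligned
  refs_na <- c(60, NA, 90, 110)
  ov3 <- outcome_vectors(segs, list_pool()["BYPASS"], refs_na)
  expect_length(ov3$BYPASS, 3)
  expect_error(outcome_vectors(list(), list_pool()["BYPASS"], numeric(0)))
  dm <- distance_matrix(ov)
  expect_equal(diag(dm), c(BYPASS = 0, BPF = 0))
  expect_equal(dm, t(dm))
})
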