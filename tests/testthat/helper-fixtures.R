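# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

tone <- function(f, fs = 100, n = 1000, amp = 1, phase = 0)
  amp * sin(2 * pi * f * (seq_len(n) - 1) / fs + phase)

# band power oracle: padded periodogram, independent of the filters under test
band_power <- function(x, fs, lo, hi, nfft = 8192) {
  x <- x - mean(x)
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  half <- floor(nfft / 2)
  f <- (1:half) * fs / nfft
  p <- Mod(X[2:(half + 1)])^2
  sum(p[f >= lo & f <= hi])
}

# clean synthetic pulse train at a fixed heart rate (two-Gaussian beats)
pulse_wave <- function(bpm, fs = 100, dur_s = 10) {
  period <- 60 / bpm
  t <- (seq_len(round(fs * dur_s)) - 1) / fs
  x <- numeric(length(t))
  for (t0 in seq(0, dur_s + period, by = period)) {
    tt <- t - t0
    x <- x + exp(-(tt - 0.20 * period)^2 / (2 * (0.07 * period)^2)) +
      0.3 * exp(-(tt - 0.45 * period)^2 / (2 * (0.12 * period)^2))
  }
  x
}

# the default 12-subject corpus at seed 1 (the package's stated world);
# expensive, so built once per test run
default_corpus <- function() fixture("default_corpus", function() {
  sessions <- generate_corpus(12, seed = 1)
  corpus_segments(sessions, reference = "truth")
})

# a small corpus for framework-level tests: 4 subjects, 2 protocol blocks
small_corpus <- function() fixture("small_corpus", function() {
  ps <- protocol_spec(static_s = 120, typing_s = 60, repetitions = 2L)
  sessions <- generate_corpus(4, ps, seed = 42, severity_range = c(1, 8))
  corpus_segments(sessions, reference = "truth")
})

# severity tiers of the default log-spaced 1..8 severity grid
corpus_severities <- function(n = 12) exp(seq(log(1), log(8), length.out = n))

# per-segment usable fraction of `ids` algorithms over given segment indices
rescue_rate <- function(corp, idx, algorithm_id, thr = 5) {
  est <- vapply(idx, function(i)
    tryCatch(estimate_hr_ppg(apply_algorithm(corp$segments[[i]],
                                             algorithm_id))$bpm,
             error = function(e) NA_real_), 0)
  mean(abs(est - corp$reference_bpm[idx]) <= thr, na.rm = TRUE)
}

# quick single-config training grid (keeps desk-scale runtime; the full
# default grid is exercised on tiny planted data instead)
fast_tc <- function(seed = 1L)
  training_config(grid = expand.grid(max_depth = 3L, eta = 0.3,
                                     nrounds = 100L),
                  seed = seed)

# planted separable SQI-like features: label depends only on the std column
planted_features <- function(n = 400, seed = 7) {
  set.seed(seed)
  X <- matrix(rnorm(n * 14), n, 14, dimnames = list(NULL, sqi_names()))
  X[, "std"] <- runif(n, 0, 2)
  y <- as.integer(X[, "std"] < 1)
  groups <- rep(sprintf("g%d", 1:8), length.out = n)
  list(X = X, y = y, groups = groups)
}
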