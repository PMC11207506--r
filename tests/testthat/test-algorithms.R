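test_that("the pool lists nine algorithms with the published energies", {
  pool <- list_pool()
  expect_length(pool, 9)
  expect_equal(pool$BYPASS$energy_mJ, 0)
  expect_equal(pool$WVL$energy_mJ, 9.73)
  expect_equal(pool$SSA$energy_mJ, 28767.42)
  expect_equal(pool$SVDTFD$energy_mJ, 333.03)
  ov <- list_pool(c(BPF = 1.5))
  expect_equal(ov$BPF$energy_mJ, 1.5)
  expect_error(list_pool(c(NOPE = 1)), "unknown algorithm")
  expect_error(algorithm_spec("BYPASS", energy_mJ = 3), "BYPASS energy")
})

test_that("every algorithm preserves length and BYPASS is the identity", {
  set.seed(11)
  x <- pulse_wave(75) + 0.05 * rnorm(1000)
  seg <- ppg_segment(x, fs = 100)
  for (spec in list_pool()) {
    y <- apply_algorithm(seg, spec)
    expect_length(y$samples, 1000)
  }
  expect_identical(apply_algorithm(seg, "BYPASS")$samples, x)
  expect_error(apply_algorithm(numeric(10), "BPF", fs = 100), "too short")
  expect_error(algorithm_spec("XXX"), "unknown algorithm")
})

test_that("Butterworth filters meet their spectral contracts", {
  fs <- 100
  # passband amplitude within 1% (squared response of forward-backward)
  y <- apply_algorithm(tone(1.2), "BPF", fs = fs)
  expect_equal(stats::sd(y[200:800]) / stats::sd(tone(1.2)[200:800]), 1,
               tolerance = 0.01)
  # DC removal: constant in, ~zero out
  y <- apply_algorithm(rep(7, 1000), "HPF", fs = fs)
  expect_lt(max(abs(y[51:950])), 1e-3 * 7)
  # stopband/passband on two-tone inputs (tones >= 1 octave from cutoffs)
  checks <- list(
    list(id = "BPF", pass = 2, stop = 30),
    list(id = "LPF", pass = 1.2, stop = 10),
    list(id = "HPF", pass = 2, stop = 0.1))
  for (ck in checks) {
    x <- tone(ck$pass) + tone(ck$stop)
    y <- apply_algorithm(x, ck$id, fs = fs)
    drop_stop <- 10 * log10(band_power(x, fs, ck$stop * 0.97, ck$stop * 1.03) /
                            band_power(y, fs, ck$stop * 0.97, ck$stop * 1.03))
    chg_pass <- 10 * log10(band_power(x, fs, ck$pass * 0.97, ck$pass * 1.03) /
                           band_power(y, fs, ck$pass * 0.97, ck$pass * 1.03))
    expect_gt(drop_stop, 20)
    expect_lt(abs(chg_pass), 1)
  }
})

test_that("Butterworth filters are linear and zero-phase", {
  set.seed(2)
  x <- rnorm(1000); y <- rnorm(1000)
  for (id in c("BPF", "LPF", "HPF")) {
    lhs <- apply_algorithm(2 * x + 3 * y, id, fs = 100)
    rhs <- 2 * apply_algorithm(x, id, fs = 100) +
      3 * apply_algorithm(y, id, fs = 100)
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
  # zero phase: spectral peak of a filtered pulse train does not move
  x <- pulse_wave(80)
  for (id in c("BPF", "LPF", "HPF")) {
    f0 <- estimate_hr_ppg(x, fs = 100)$peak_freq_hz
    f1 <- estimate_hr_ppg(apply_algorithm(x, id, fs = 100), fs = 100)$peak_freq_hz
    expect_equal(f0, f1, tolerance = 0.02)
  }
})

test_that("SSA separates sub-1 Hz drift from in-band content", {
  fs <- 100
  x <- tone(0.3) + tone(1.5)
  y <- apply_algorithm(x, "SSA", fs = fs)
  drop_drift <- 10 * log10(band_power(x, fs, 0.25, 0.35) /
                           band_power(y, fs, 0.25, 0.35))
  chg_tone <- 10 * log10(band_power(x, fs, 1.45, 1.55) /
                         band_power(y, fs, 1.45, 1.55))
  expect_gt(drop_drift, 20)
  expect_lt(abs(chg_tone), 1)
})

test_that("WVL removes baseline and top-octave noise, keeps cardiac band", {
  fs <- 100
  x <- tone(0.3) + tone(1.5) + 0.2 * tone(30)
  y <- apply_algorithm(x, "WVL", fs = fs)
  expect_gt(10 * log10(band_power(x, fs, 0.25, 0.35) /
                       band_power(y, fs, 0.25, 0.35)), 20)
  expect_gt(10 * log10(band_power(x, fs, 29, 31) /
                       band_power(y, fs, 29, 31)), 15)
  expect_lt(abs(10 * log10(band_power(x, fs, 1.45, 1.55) /
                           band_power(y, fs, 1.45, 1.55))), 1)
})

test_that("db8 filter bank is a valid orthogonal wavelet pair", {
  g <- qappg:::DB8_SCALING
  expect_length(g, 16)
  expect_equal(sum(g), sqrt(2), tolerance = 1e-12)
  expect_equal(sum(g^2), 1, tolerance = 1e-12)
  for (k in 1:7)
    expect_equal(sum(g[seq_len(16 - 2 * k)] * g[seq_len(16 - 2 * k) + 2 * k]),
                 0, tolerance = 1e-12)
  # perfect reconstruction of the analysis/synthesis pyramid
  set.seed(5)
  x <- rnorm(1000)
  dec <- qappg:::modwt_db8(x, 6)
  expect_equal(qappg:::imodwt_db8(dec), x, tolerance = 1e-9)
})

test_that("decomposition methods keep a clean pulse train intact", {
  # SSA/EMD/CUB/WVL must not destroy in-band content: HR shift < 2 BPM
  for (bpm in c(60, 96)) {
    x <- pulse_wave(bpm)
    for (id in c("SSA", "EMD", "CUB", "WVL", "SVDTFD")) {
      est <- estimate_hr_ppg(apply_algorithm(x, id, fs = 100), fs = 100)$bpm
      expect_lt(abs(est - bpm), 2)
    }
  }
})

test_that("EMD removes slow trend and the residue", {
  fs <- 100
  t <- (0:999) / fs
  x <- tone(1.5) + 3 * exp(-t / 4) # decaying trend, dominant well below 0.25 Hz
  y <- apply_algorithm(x, "EMD", fs = fs)
  expect_gt(10 * log10(band_power(x, fs, 0.01, 0.2) /
                       band_power(y, fs, 0.01, 0.2)), 10)
  expect_lt(abs(10 * log10(band_power(x, fs, 1.45, 1.55) /
                           band_power(y, fs, 1.45, 1.55))), 1)
  # decomposition is additive: imfs + residue == signal
  dec <- emd_decompose(x)
  expect_equal(Reduce(`+`, dec$imfs) + dec$residue, x, tolerance = 1e-9)
})

test_that("SVDTFD keeps the dominant periodic component, sheds noise", {
  set.seed(3)
  fs <- 100
  x <- tone(1.5) + rnorm(1000, 0, 0.5)
  y <- apply_algorithm(x, "SVDTFD", fs = fs)
  chg_tone <- 10 * log10(band_power(x, fs, 1.45, 1.55) /
                         band_power(y, fs, 1.45, 1.55))
  expect_lt(abs(chg_tone), 1)
  expect_lt(stats::var(y), stats::var(x))   # net noise reduction
})
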