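fs <- 256

test_that("EDF files round-trip through the reader and writer", {
  set.seed(1)
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  sig <- cbind(
    Fp1 = 50 * sin(2 * pi * 10 * t) + 5 * rnorm(length(t)),
    Cz = 20 * sin(2 * pi * 4 * t)
  )
  rec <- eeg_record(sig, fs, seizure_onsets = c(12.5))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$sampling_rate, fs)
  expect_equal(ncol(back$signals), 2)
  expect_equal(nrow(back$signals), length(t))
  expect_equal(back$seizure_onsets, 12.5)
  # 16-bit quantisation: relative error well below 1e-3 of the range
  for (j in 1:2) {
    expect_lt(max(abs(back$signals[, j] - sig[, j])) / diff(range(sig[, j])),
              1e-3)
  }
})

test_that("the bandpass design passes the EEG band and kills drift and DC", {
  b <- design_bandpass(fs, 0.5, 75)
  g <- lttcal:::fir_gain(b, c(0, 0.1, 10, 40), fs)
  expect_lt(g[1], 0.01) # DC
  expect_lt(g[2], 0.1) # 0.1 Hz drift: >= 20 dB down per pass
  expect_gt(g[3], 0.95) # 10 Hz in-band
  expect_gt(g[4], 0.95) # 40 Hz in-band
  expect_error(design_bandpass(fs, 0.5, 200), "Nyquist")
})

test_that("zero-phase filtering preserves in-band signals, removes offsets", {
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  rec <- eeg_record(cbind(ch1 = x + 100, ch2 = rep(3, length(t))), fs)
  filt <- bandpass_filter(rec)
  mid <- 2000:3000
  expect_gt(max(abs(filt$signals[mid, 1])), 0.95) # sinusoid kept
  expect_lt(max(abs(filt$signals[mid, 1] - x[mid])), 0.05) # offset gone
  expect_lt(max(abs(filt$signals[mid, 2])), 1e-3) # constant channel ~ 0
})

test_that("spectral features concentrate where the signal lives", {
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t) # alpha band
  bp <- band_power_fractions(x, fs)
  expect_gt(bp[["alpha"]], 0.9)
  expect_true(all(bp[c("delta", "theta", "beta", "gamma")] < 0.05))
  expect_true(all(bp >= 0) && sum(bp) <= 1)
  expect_lt(spectral_entropy(x, fs), 0.3) # pure tone: low entropy
  set.seed(6)
  expect_gt(spectral_entropy(rnorm(length(t)), fs), 0.5) # noise: high
})

test_that("Hjorth parameters match the sinusoid closed form", {
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  for (f in c(5, 10)) {
    hj <- hjorth_params(sin(2 * pi * f * t), fs)
    expect_equal(hj[["mobility"]], 2 * pi * f, tolerance = 0.02)
    expect_equal(hj[["complexity"]], 1, tolerance = 0.02)
  }
  expect_equal(hjorth_params(rep(1, 100), fs),
               c(mobility = 0, complexity = 0))
})

test_that("DFA and Higuchi agree with white-noise asymptotics", {
  set.seed(9)
  x <- rnorm(6 * fs)
  expect_equal(dfa_exponent(x), 0.5, tolerance = 0.15)
  expect_equal(higuchi_fd(x), 2, tolerance = 0.15)
  # Brownian motion scales with exponent ~ 1.5
  expect_equal(dfa_exponent(cumsum(rnorm(6 * fs))), 1.5, tolerance = 0.2)
})

test_that("scale-free features are invariant to amplitude scaling", {
  set.seed(10)
  x <- rnorm(6 * fs) + sin(2 * pi * 8 * seq(0, 6 - 1 / fs, by = 1 / fs))
  for (feat in list(
    function(z) band_power_fractions(z, fs),
    function(z) spectral_entropy(z, fs),
    function(z) dfa_exponent(z),
    function(z) higuchi_fd(z),
    function(z) hjorth_params(z, fs)[["complexity"]]
  )) {
    expect_equal(feat(1000 * x), feat(x), tolerance = 1e-8)
  }
})

test_that("feature extraction windows the record as documented", {
  dur <- 21
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  sig <- cbind(a = sin(2 * pi * 10 * t), b = rep(0, length(t)))
  rec <- eeg_record(sig, fs)
  feats <- extract_features(rec)
  n_win <- floor((dur - 6) / 3) + 1
  expect_equal(nrow(feats), n_win * 2)
  expect_equal(unique(feats$window_start), (seq_len(n_win) - 1) * 3)
  # flat channel flagged, all features zeroed
  flat <- feats[feats$channel == "b", ]
  expect_true(all(flat$zero_variance))
  expect_true(all(flat$alpha == 0 & flat$higuchi_fd == 0))
  live <- feats[feats$channel == "a", ]
  expect_true(all(live$alpha > 0.9))
  expect_error(extract_features(eeg_record(cbind(x = rnorm(fs)), fs)),
               "shorter")
})

test_that("preictal labelling covers 60 min to 30 s before onset", {
  starts <- seq(0, 4000, by = 3)
  onset <- 61 * 60 # 3660 s
  lab <- label_preictal(4200, onset, starts)
  on <- starts[as.integer(lab) == 1]
  expect_equal(min(on), 60) # first start >= onset - 3600
  expect_lte(max(on), onset - 30 - 3) # strict 30 s exclusion
  expect_equal(max(on), 3627)
  # a window starting 10 s before onset is excluded
  expect_equal(as.integer(label_preictal(4000, 1000, 990)), 0L)
  # no seizures -> all zero
  expect_true(all(label_preictal(4000, numeric(0), starts) == 0))
  expect_warning(label_preictal(100, 200, c(0, 3)), "clipped")
})
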