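make_sine_trials <- function(freqs, fs = 128, dur = 9, amp = 1) {
  n <- round(dur * fs)
  tt <- (seq_len(n) - 1) / fs
  dat <- array(0, c(length(freqs), 1, n))
  for (i in seq_along(freqs)) dat[i, 1, ] <- amp * sin(2 * pi * freqs[i] * tt)
  trial_set(dat, fs = fs, labels = rep(c(1, -1), length.out = length(freqs)))
}

# steady-state amplitude, measured away from filter edge transients
mid_amp <- function(ts, trial = 1) max(abs(ts$data[trial, 1, 300:900]))

test_that("0.5-30 Hz band-pass passes 10 Hz, rejects 50 Hz and DC", {
  ts <- make_sine_trials(c(10, 50))
  flt <- bandpass(ts, 0.5, 30)
  expect_lt(abs(mid_amp(flt, 1) - 1), 0.05)          # passband within 5%
  expect_lt(20 * log10(mid_amp(flt, 2)), -20)         # stopband >= 20 dB down
  dc <- make_sine_trials(0)                           # sin(0) = 0; use constant
  dc$data[1, 1, ] <- 1
  expect_lt(mid_amp(bandpass(dc, 0.5, 30)), 0.05)     # 0 Hz outside the band
})

test_that("band-pass filtering is zero-phase and linear", {
  ts <- make_sine_trials(10)
  flt <- bandpass(ts, 0.5, 30)
  # zero group delay: the filtered 10 Hz sine stays in phase with the input
  mid <- 300:900
  phase_corr <- sum(flt$data[1, 1, mid] * ts$data[1, 1, mid]) /
    sqrt(sum(flt$data[1, 1, mid]^2) * sum(ts$data[1, 1, mid]^2))
  expect_gt(phase_corr, 0.999)

  set.seed(3)
  a <- 1.7; b <- -0.6
  x <- make_sine_trials(8); z <- make_sine_trials(14)
  comb <- x; comb$data <- a * x$data + b * z$data
  lhs <- bandpass(comb, 0.5, 30)$data
  rhs <- a * bandpass(x, 0.5, 30)$data + b * bandpass(z, 0.5, 30)$data
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("band-pass rejects invalid bands and too-short trials", {
  ts <- make_sine_trials(10)
  expect_error(bandpass(ts, 30, 0.5), "lo < hi")
  expect_error(bandpass(ts, 0.5, 64), "Nyquist")
  short <- trial_set(array(rnorm(2 * 1 * 32), c(2, 1, 32)), 128, c(1, -1))
  expect_error(bandpass(short, 0.5, 30), "too short")
})

test_that("epoch cuts the expected sample counts and updates t0", {
  ts <- make_sine_trials(10)                   # 9 s at 128 Hz = 1152 samples
  e <- epoch(ts, 4, 9)
  expect_identical(dim(e$data)[3], 640L)       # 5 s x 128 Hz
  expect_identical(e$t0, 4)
  full <- epoch(ts, 0, 9)
  expect_identical(dim(full$data)[3], 1152L)
  expect_error(epoch(ts, 4, 10), "outside")
})

test_that("band-power features have closed-form values on pure sinusoids", {
  # amplitude-a sinusoid has variance a^2/2; its mu-band log power is log(a^2/2)
  a <- 3
  n <- round(9 * 128); tt <- (seq_len(n) - 1) / 128
  dat <- array(0, c(2, 2, n))
  dat[, 1, ] <- rep(a * sin(2 * pi * 10 * tt), each = 2)
  dat[, 2, ] <- rnorm(2 * n, sd = 0.1)
  ts <- trial_set(dat, 128, c(1, -1), c("C3", "C4"))
  fm <- extract_features(ts, feature_spec(bands = list(c(8, 12)), window = c(4, 9)))
  expect_equal(dim(fm$X), c(2L, 2L))
  # band-edge roll-off of the order-4 filter trims a little sinusoid power
  expect_lt(abs(fm$X[1, 1] - log(a^2 / 2)), 0.05)
})

test_that("feature dimensions follow channels x bands and the flatten contract", {
  ts <- tiny_trial_set(n_per_class = 2L)
  bp <- extract_features(ts, feature_spec(bands = list(c(8, 12), c(18, 26))))
  expect_identical(ncol(bp$X), 6L)             # 3 channels x 2 bands
  fl <- extract_features(ts, feature_spec(mode = "flatten", window = c(4, 9),
                                          downsample_factor = 4L))
  expect_identical(ncol(fl$X), 3L * 160L)      # 3 channels x 640/4
  expect_identical(bp$y, ts$labels)
  expect_error(feature_spec(bands = list()), "at least one band")
})

test_that("feature extraction is permutation-equivariant over trials", {
  ts <- tiny_trial_set(n_per_class = 3L, seed = 2L)
  perm <- c(4, 1, 6, 2, 5, 3)
  tsp <- ts
  tsp$data <- ts$data[perm, , , drop = FALSE]
  tsp$labels <- ts$labels[perm]
  f1 <- extract_features(ts, feature_spec())
  f2 <- extract_features(tsp, feature_spec())
  expect_equal(f2$X, f1$X[perm, ], tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(f2$y, f1$y[perm])
})

test_that("z-scoring uses training statistics only", {
  fm <- generate_gaussian_features(30, 4, separation = 1, seed = 4)
  nz <- zscore_fit(fm)
  z <- zscore_apply(nz, fm)
  expect_true(all(abs(colMeans(z$X)) < 1e-10))
  expect_equal(unname(apply(z$X, 2, stats::var)), rep(1, 4), tolerance = 1e-10)
  heldout <- generate_gaussian_features(200, 4, separation = 1, seed = 99)
  zh <- zscore_apply(nz, heldout)
  expect_true(all(abs(colMeans(zh$X)) < 0.5))          # near, not exactly, 0
  expect_false(any(colMeans(zh$X) == 0))
  # constant feature: centred, scale forced to 1
  cfm <- feature_matrix(cbind(rep(2, 10), rnorm(10)), rep(c(1, -1), 5))
  zc <- zscore_apply(zscore_fit(cfm), cfm)
  expect_identical(unname(zc$X[, 1]), rep(0, 10))
  expect_error(zscore_apply(nz, cfm), "features")
})
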