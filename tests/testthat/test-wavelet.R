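test_that("band_frequencies spans the closed band evenly", {
  f <- band_frequencies(72.8, 1.83, 5)
  expect_length(f, 5)
  expect_equal(f[1], 72.8 / 1.83)
  expect_equal(f[5], 72.8 * 1.83)
  expect_equal(round(range(f), 1), c(39.8, 133.2))
  expect_equal(diff(f), rep(diff(f)[1], 4))

  expect_equal(band_frequencies(10, 1, 3), c(10, 10, 10))
  expect_equal(band_frequencies(8, 2, 3), c(4, 10, 16))
  expect_equal(band_frequencies(5, 3, 1), 5)
  expect_error(band_frequencies(-1, 2, 3), "positive")
  expect_error(band_frequencies(10, 0.5, 3), ">= 1")
  expect_error(band_frequencies(10, 2, 0), "integer")
})

test_that("a unit sinusoid has envelope 1 across the band (normalization)", {
  for (f in c(2, 5, 10, 50, 100, 200)) {
    x <- timeseries(sin(2 * pi * f * seq(0, 8, by = 1e-3)), rate = 1000)
    env <- wavelet_envelope(x, f)
    m <- ts_valid_mask(env, edge = wavelet_window(f))
    expect_lt(max(abs(env$samples[m] - 1)), 0.02, label = paste(f, "Hz"))
  }
})

test_that("zero, constant and scaled inputs behave as the transform demands", {
  z <- wavelet_envelope(timeseries(rep(0, 3000), 1000), 10)
  expect_lt(max(z$samples), 1e-12)
  cst <- wavelet_envelope(timeseries(rep(7.3, 3000), 1000), 10)
  expect_lt(max(cst$samples), 1e-10)
  # linearity in the amplitude
  s <- sin(2 * pi * 7 * seq(0, 4, by = 1e-3)) + 0.3 * rnorm(4001)
  e1 <- wavelet_envelope(timeseries(s, 1000), 7)$samples
  e2 <- wavelet_envelope(timeseries(2.5 * s, 1000), 7)$samples
  expect_equal(e2, 2.5 * e1, tolerance = 1e-12)
})

test_that("wavelet preconditions are enforced", {
  x <- timeseries(rnorm(500), rate = 1000)
  expect_error(wavelet_envelope(x, 600), "Nyquist")
  expect_error(wavelet_envelope(timeseries(rnorm(100), 1000), 5),
               "shorter than the wavelet window")
})

test_that("FFT convolution matches direct trapezoidal integration", {
  set.seed(5)
  x1 <- timeseries(rnorm(1000), rate = 1000)   # 1-s test signal
  for (f in c(40, 150)) {
    idx <- seq(350L, 650L, by = 25L)
    direct <- oracle_envelope(x1, f, idx = idx)
    fftv <- wavelet_envelope(x1, f)$samples[idx]
    expect_lt(max(abs(fftv - direct) / direct), 1e-6,
              label = paste(f, "Hz"))
  }
  # low frequency needs a longer signal for interior points
  x2 <- timeseries(rnorm(2500), rate = 1000)
  idx <- seq(800L, 1700L, by = 100L)
  direct <- oracle_envelope(x2, 10, idx = idx)
  fftv <- wavelet_envelope(x2, 10)$samples[idx]
  expect_lt(max(abs(fftv - direct) / direct), 1e-6)
})

test_that("band envelope reduces per sample and answers single tones", {
  t <- seq(0, 6, by = 1e-3)
  f0 <- sqrt(60 * 100)
  x <- timeseries(sin(2 * pi * f0 * t), rate = 1000)
  env <- band_envelope(x, c(60, 100), n_wavelets = 5, reduce = "max")
  m <- ts_valid_mask(env, edge = wavelet_window(60))
  expect_lt(max(abs(env$samples[m] - 1)), 0.05)
  # mean-reduce is bounded above by max-reduce
  env_m <- band_envelope(x, c(60, 100), n_wavelets = 5, reduce = "mean")
  expect_true(all(env_m$samples <= env$samples + 1e-12))
  z <- band_envelope(timeseries(rep(0, 3000), 1000), c(2, 4))
  expect_lt(max(z$samples), 1e-12)
})

test_that("gaussian smoothing is unit-area, identity at T = 0", {
  x <- timeseries(rep(4.2, 1000), rate = 1000)
  expect_equal(gaussian_smooth(x, 0.05)$samples, x$samples,
               tolerance = 1e-12)
  y <- timeseries(rnorm(500), rate = 1000)
  expect_identical(gaussian_smooth(y, 0), y)
  expect_error(gaussian_smooth(y, -1), "nonnegative")
  # impulse response reproduces the truncated normalized kernel
  imp <- timeseries(c(rep(0, 500), 1, rep(0, 499)), rate = 1000)
  g <- gaussian_smooth(imp, 0.01)
  k <- dnorm(-40:40, sd = 10); k <- k / sum(k)
  expect_equal(g$samples[461:541], k, tolerance = 1e-12)
  expect_equal(sum(g$samples), 1, tolerance = 1e-9)
})

test_that("MUA is the rectified 0.3-3 kHz band", {
  rate <- 20000
  t <- seq(0, 0.5, by = 1 / rate)
  z <- mua_trace(timeseries(rep(0, 5000), rate))
  expect_equal(max(z$samples), 0)
  inband <- mua_trace(timeseries(sin(2 * pi * 1000 * t), rate))
  expect_equal(mean(inband$samples), 2 / pi, tolerance = 0.02)
  low <- mua_trace(timeseries(sin(2 * pi * 10 * t), rate))
  expect_lt(mean(low$samples), 0.02)
  expect_error(mua_trace(timeseries(rnorm(1000), 4000)), "too low")
})

test_that("tf_spectrum peaks at the tone and honors line-noise blanking", {
  x <- timeseries(sin(2 * pi * 10 * seq(0, 10, by = 1e-3)), rate = 1000)
  freqs <- c(3, 10, 30, 49, 51, 80)
  sp <- tf_spectrum(x, freqs, blank = c(48, 52))
  expect_equal(sp$envelope[sp$freq == 10], 1, tolerance = 0.02)
  expect_true(all(sp$envelope[sp$freq %in% c(3, 30, 80)] < 0.1))
  expect_true(all(is.na(sp$envelope[sp$blanked])))
  expect_identical(sp$blanked, freqs >= 48 & freqs <= 52)
  expect_error(tf_spectrum(x, numeric(0)), "nonempty")
  z <- tf_spectrum(timeseries(rep(0, 4000), 1000), c(5, 20))
  expect_equal(z$envelope, c(0, 0), tolerance = 1e-12)
})
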