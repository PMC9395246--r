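test_that("bin_by_nsi averages within bins and suppresses sparse bins", {
  df <- tibble::tibble(nsi = c(rep(0.4, 7), rep(1.5, 6), rep(2.5, 5)),
                       y = c(rep(1, 7), rep(2, 6), rep(3, 5)))
  b <- bin_by_nsi(df, y, nsi, bin_width = 1, min_count = 5)
  # the 5-episode bin is suppressed ("more than five")
  expect_equal(b$nsi_bin, c(0.5, 1.5))
  expect_equal(b$mean, c(1, 2))
  expect_equal(b$n, c(7L, 6L))
  # identity: bin means of the nsi values themselves are the bin centers
  set.seed(6)
  df2 <- tibble::tibble(nsi = runif(500, 0, 10))
  b2 <- bin_by_nsi(df2, nsi, nsi)
  expect_true(all(abs(b2$mean - b2$nsi_bin) <= 0.5))
  expect_error(bin_by_nsi(tibble::tibble(a = 1:3, b = 1:2), b, a))
})

test_that("a planted episode-level coupling slope is recovered from bins", {
  set.seed(12)
  nsi <- runif(600, 0, 15)
  vm <- -70 + 1.5 * nsi + rnorm(600, sd = 1)
  b <- bin_by_nsi(tibble::tibble(nsi = nsi, vm = vm), vm)
  fit <- lm(mean ~ nsi_bin, data = b)
  expect_equal(unname(coef(fit)[2]), 1.5, tolerance = 0.1)
})

test_that("distribution features summarise validated episodes", {
  ep <- tibble::tibble(
    t_center = (1:10) / 5,
    nsi = c(rep(5, 6), rep(NA, 4)),
    label = c(rep("nonrhythmic", 6), rep("unclassified", 4)),
    validated = c(rep(TRUE, 6), rep(FALSE, 4)))
  f <- distribution_features(ep)
  expect_equal(f$mu_NSI, 5)
  expect_equal(f$sigma_NSI, 0)
  expect_equal(f$F_rhythmic, 0)
  expect_true(is.na(f$mu_neg) && is.na(f$sigma_neg))

  # bimodal schedule: 40% rhythmic at -8, 60% nonrhythmic at +6
  ep2 <- tibble::tibble(
    t_center = (1:50) / 5,
    nsi = c(rep(-8, 20), rep(6, 30)),
    label = c(rep("rhythmic", 20), rep("nonrhythmic", 30)),
    validated = TRUE)
  f2 <- distribution_features(ep2)
  expect_equal(f2$F_rhythmic, 0.4)
  expect_equal(f2$mu_neg, -8)
  expect_equal(f2$mu_pos, 6)
  # permutation invariance
  f3 <- distribution_features(ep2[sample(50), ])
  expect_equal(f2, f3)
  expect_error(distribution_features(ep[!ep$validated, ]), "no validated")
})

test_that("feature regression recovers exact and null relationships", {
  set.seed(20)
  n <- 40
  rec <- tibble::tibble(
    mu_NSI = rnorm(n, 5), sigma_NSI = runif(n, 1, 4),
    F_rhythmic = runif(n), mu_pos = rnorm(n, 7), mu_neg = rnorm(n, -5),
    sigma_pos = runif(n, 0.5, 3), sigma_neg = runif(n, 0.5, 3))
  rec$cc <- 0.1 + 0.2 * rec$sigma_NSI          # exact univariate relation
  # exact fits make lm's summary grumble; that is the point of the case
  rr <- suppressWarnings(regress_cc_on_features(rec))
  top <- rr$univariate$feature[1]
  expect_equal(top, "sigma_NSI")
  expect_equal(rr$univariate$adj_r2[1], 1, tolerance = 1e-9)

  rec$cc <- rnorm(n)                           # pure noise
  rr0 <- regress_cc_on_features(rec)
  expect_lt(rr0$multiple$adj_r2, 0.35)

  # collinear features are reported by name
  rec2 <- rec
  rec2$sigma_pos <- 2 * rec2$sigma_NSI
  expect_error(regress_cc_on_features(rec2), "collinear")
})

test_that("best 3-feature subset search is exhaustive over triples", {
  set.seed(22)
  n <- 45
  rec <- tibble::tibble(
    mu_NSI = rnorm(n), sigma_NSI = rnorm(n), F_rhythmic = runif(n),
    mu_pos = rnorm(n), mu_neg = rnorm(n), sigma_pos = rnorm(n),
    sigma_neg = rnorm(n))
  rec$cc <- 0.5 * rec$sigma_NSI - 0.4 * rec$F_rhythmic +
    0.3 * rec$mu_neg + rnorm(n, sd = 0.1)
  rr <- regress_cc_on_features(rec)
  expect_setequal(rr$best_subset$features,
                  c("sigma_NSI", "F_rhythmic", "mu_neg"))
  expect_gt(rr$best_subset$adj_r2, 0.8)
})

test_that("gamma-to-delta ratio separates slow from fast tones", {
  t <- seq(0, 8, by = 1 / 400)
  slow <- gamma_delta_ratio(timeseries(sin(2 * pi * 3 * t), rate = 400))
  m <- ts_valid_mask(slow)
  expect_lt(mean(slow$samples[m], na.rm = TRUE), 0.2)
  fast <- gamma_delta_ratio(timeseries(sin(2 * pi * 50 * t), rate = 400))
  expect_gt(mean(fast$samples[ts_valid_mask(fast)], na.rm = TRUE), 5)
  # mixed tones: ratio approximates the envelope ratio
  mixed <- gamma_delta_ratio(timeseries(
    2 * sin(2 * pi * 50 * t) + 0.5 * sin(2 * pi * 3 * t), rate = 400))
  r <- mean(mixed$samples[ts_valid_mask(mixed)], na.rm = TRUE)
  # mean-reduce over [30,80] with a 50-Hz tone responds on a few wavelets
  # only, so compare against the measured single-tone responses
  e_g <- mean(band_envelope(timeseries(2 * sin(2 * pi * 50 * t), 400),
                            c(30, 80), 20, "mean")$samples[m])
  e_d <- mean(band_envelope(timeseries(0.5 * sin(2 * pi * 3 * t), 400),
                            c(2, 4), 20, "mean")$samples[m])
  expect_equal(r, e_g / e_d, tolerance = 0.1 * e_g / e_d)
  expect_error(gamma_delta_ratio(timeseries(rnorm(100), rate = 100)),
               "Nyquist")
})

test_that("the delta-modulated channel wins channel selection", {
  withr::with_seed(33L, {
    rate <- 2000
    n <- 40 * rate
    t <- (seq_len(n) - 1) / rate
    flat <- lapply(1:2, function(i) {
      carrier <- signal::filtfilt(signal::butter(4, c(40, 130) / (rate / 2),
                                                 "pass"), rnorm(n))
      timeseries(5 * carrier, rate = rate)
    })
    carrier <- signal::filtfilt(signal::butter(4, c(40, 130) / (rate / 2),
                                               "pass"), rnorm(n))
    modulated <- timeseries(5 * carrier * (1 + 0.8 * sin(2 * pi * 3 * t)),
                            rate = rate)
    sel <- select_delta_channel(list(flat[[1]], modulated, flat[[2]]))
    expect_equal(sel$index, 2L)
    expect_gt(sel$scores[2], max(sel$scores[-2]))
  })
})

test_that("population rate conserves spike counts and matches Poisson rates", {
  # a single spike integrates to one spike
  r1 <- population_rate(5.0, 0, 10)
  expect_equal(sum(r1$samples) * 0.005, 1, tolerance = 0.01)
  expect_equal(r1$units, "Hz")
  # 50 units at 20 Hz pool to ~1000 Hz
  withr::with_seed(44L, {
    spikes <- lapply(1:50, function(i) sort(runif(20 * 30, 0, 30)))
    r <- population_rate(spikes, 0, 30)
    expect_equal(mean(r$samples), 1000, tolerance = 0.05 * 1000)
    total <- sum(r$samples) * 0.005
    expect_equal(total, 50 * 600, tolerance = 0.01 * 50 * 600)
  })
  expect_warning(r0 <- population_rate(numeric(0), 0, 5), "no spikes")
  expect_equal(max(r0$samples), 0)
})
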