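test_that("Vm-based NSI obeys its closed forms", {
  vc <- compute_vm_nsi(timeseries(rep(-70, 5000), rate = 1000,
                                  units = "mV"))
  expect_lt(max(abs(vc$nsi$samples)), 1e-9)
  expect_equal(vc$p0, -70)

  t <- seq(0, 10, by = 1e-3)
  vm <- timeseries(-70 + 5 * (1 + sin(2 * pi * 3 * t)), rate = 1000,
                   units = "mV")
  nv <- compute_vm_nsi(vm)
  m <- ts_valid_mask(nv$nsi, edge = 1.2)
  expect_true(all(nv$nsi$samples[m] <= 0))
  expect_equal(mean(nv$nsi$samples[m]), -10, tolerance = 0.5)
  expect_error(compute_vm_nsi(timeseries(rnorm(100), rate = 500)),
               "1 kHz")
})

test_that("the scale factor is the through-origin slope on concordant pairs", {
  v <- seq(-5, 5, length.out = 101)
  paired <- tibble::tibble(t_center = seq_along(v) / 5, nsi_vm = v,
                           nsi_plfp = 0.5 * v, validated_plfp = TRUE,
                           validated_vm = TRUE, both_validated = TRUE)
  f <- fit_scale_factor(paired)
  expect_equal(f$F, 0.5, tolerance = 1e-12)
  # discordant-sign pairs do not enter the fit
  paired2 <- dplyr::bind_rows(paired, tibble::tibble(
    t_center = 100 + 1:20, nsi_vm = -(1:20), nsi_plfp = 1:20,
    validated_plfp = TRUE, validated_vm = TRUE, both_validated = TRUE))
  f2 <- fit_scale_factor(paired2)
  expect_equal(f2$F, f$F, tolerance = 1e-12)
  expect_equal(f2$n_discordant, 20L)
  expect_error(fit_scale_factor(paired[0, ]), "concordant")
})

test_that("noisy proportional coupling is recovered within 10%", {
  set.seed(14)
  v <- runif(500, -10, 20)
  paired <- tibble::tibble(t_center = 1:500, nsi_vm = v,
                           nsi_plfp = 0.8 * v + rnorm(500, sd = 1),
                           validated_plfp = TRUE, validated_vm = TRUE,
                           both_validated = TRUE)
  f <- fit_scale_factor(paired)
  expect_equal(f$F, 0.8, tolerance = 0.1)
})

test_that("accuracy is 100% for proportional pairs and monotone in tolerances", {
  v <- seq(-5, 5, length.out = 101)
  paired <- tibble::tibble(t_center = seq_along(v) / 5, nsi_vm = v,
                           nsi_plfp = 0.5 * v, validated_plfp = TRUE,
                           validated_vm = TRUE, both_validated = TRUE)
  acc <- evaluate_accuracy(paired, 0.5, p_tol = 2.85, vm_tol = 2)
  expect_equal(acc$accuracy, 100)

  set.seed(8)
  noisy <- dplyr::mutate(paired, nsi_plfp = nsi_plfp + rnorm(101, sd = 3))
  grid <- expand.grid(p = c(0.5, 1, 2.85, 5), v = c(0.5, 1, 2, 4))
  accs <- matrix(mapply(function(p, v)
    evaluate_accuracy(noisy, 0.5, p, v)$accuracy, grid$p, grid$v),
    nrow = 4)
  expect_true(all(diff(accs) >= 0))        # widening p_tol
  expect_true(all(diff(t(accs)) >= 0))     # widening vm_tol
})

test_that("misclassification categories partition the errors exactly", {
  set.seed(15)
  paired <- tibble::tibble(
    t_center = 1:400, nsi_vm = runif(400, -8, 12),
    nsi_plfp = runif(400, -10, 15),
    validated_plfp = TRUE, validated_vm = TRUE, both_validated = TRUE)
  acc <- evaluate_accuracy(paired, 0.7, p_tol = 1, vm_tol = 0.5)
  n_wrong <- sum(!acc$per_episode$correct)
  expect_equal(sum(acc$misclass_breakdown$n), n_wrong)
  if (n_wrong > 0) expect_equal(sum(acc$misclass_breakdown$percent), 100)
})

test_that("accuracy is invariant to joint rescaling of the pLFP axis", {
  set.seed(16)
  paired <- tibble::tibble(
    t_center = 1:300, nsi_vm = runif(300, -8, 12),
    nsi_plfp = runif(300, -10, 15),
    validated_plfp = TRUE, validated_vm = TRUE, both_validated = TRUE)
  a1 <- evaluate_accuracy(paired, 0.7, p_tol = 2.85, vm_tol = 2)
  k <- 3.7
  scaled <- dplyr::mutate(paired, nsi_plfp = k * nsi_plfp)
  a2 <- evaluate_accuracy(scaled, k * 0.7, p_tol = k * 2.85, vm_tol = 2)
  expect_equal(a2$accuracy, a1$accuracy)
  expect_equal(a2$misclass_breakdown$n, a1$misclass_breakdown$n)
})

test_that("pLFP- and Vm-based labels agree on clean synthetic episodes", {
  fx <- fixture_rec()
  ep_v <- validate_episodes(compute_vm_nsi(fx$rec$vm))
  paired <- pair_episodes(fx$episodes, ep_v)
  d <- dplyr::filter(paired, both_validated)
  expect_gt(nrow(d), 100)
  agree <- mean((d$nsi_vm <= 0) == (d$nsi_plfp <= 0))
  expect_gte(agree, 0.9)
  f <- fit_scale_factor(paired)
  acc <- evaluate_accuracy(paired, f)
  expect_gt(acc$accuracy, 80)
  g <- glance(acc)
  expect_equal(g$accuracy, acc$accuracy)
})

test_that("generator coupling asymmetry yields the expected dominant error", {
  # rhythmic epochs with weak pLFP delta signatures but a full-size Vm
  # oscillation: the pLFP misses rhythmicity that the Vm shows
  rec <- generate_recording(synth_config(
    duration = 120, fs = 2000, seed = 31L,
    level_range_rhythmic = c(0.4, 1.2), p_rhythmic = 0.45,
    rhythmic_vm_amp = 8))
  ep_p <- validate_episodes(compute_nsi(compute_plfp(rec$lfp)))
  ep_v <- validate_episodes(compute_vm_nsi(rec$vm))
  paired <- pair_episodes(ep_p, ep_v)
  f <- fit_scale_factor(paired)
  acc <- evaluate_accuracy(paired, f)
  bd <- acc$misclass_breakdown
  expect_equal(bd$category[which.max(bd$n)], "plfp>0 & vm<=0")
})
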