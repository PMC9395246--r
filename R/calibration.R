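#' Grid search for the pLFP band and temporal smoothing
#'
#' Data-driven selection of the high-gamma band and smoothing time constant
#' against a simultaneously recorded reference signal (membrane potential).
#' Stage one evaluates, for every `(f, w)` cell, the zero-lag Pearson
#' correlation between the reference and the un-smoothed mean wavelet
#' envelope of the LFP over the band `[f/w, f*w]`, averaged over recordings;
#' the argmax gives `(f_opt, w_opt)`. Stage two sweeps the smoothing time
#' constant at that optimum; per-recording correlation curves are normalized
#' by their maximum amplitude and the value at `T = 0` is subtracted, and
#' `T_opt` maximizes the mean normalized curve.
#'
#' @param pairs List of recordings, each a list with elements `lfp` and `vm`
#'   ([timeseries()] objects at a common rate and equal length).
#' @param f_grid Root frequencies to evaluate (Hz).
#' @param w_grid Width factors to evaluate (>= 1).
#' @param T_grid Smoothing time constants to sweep (s); must contain 0.
#'   `NULL` skips stage two.
#' @param n_wavelets Wavelets per band (default 20, as in the search).
#' @return A list of class `nsi_band_search`: `cc_grid` (tibble `f`, `w`,
#'   `cc` averaged over recordings), `f_opt`, `w_opt`, and when `T_grid` is
#'   given `cc_vs_T` (tibble `recording`, `T`, `cc`, `ncc`) and `T_opt`.
#' @export
band_grid_search <- function(pairs, f_grid, w_grid, T_grid = NULL,
                             n_wavelets = 20) {
  stopifnot(length(pairs) >= 1, length(f_grid) >= 1, length(w_grid) >= 1)
  for (p in pairs) {
    if (length(p$lfp$samples) != length(p$vm$samples) ||
        abs(p$lfp$rate - p$vm$rate) > 1e-9)
      stop("each (lfp, vm) pair must be simultaneous at a common rate",
           call. = FALSE)
  }
  cells <- tidyr::expand_grid(f = as.numeric(f_grid), w = as.numeric(w_grid))
  cc_rec <- purrr::pmap(cells, function(f, w) {
    vapply(pairs, function(p) {
      env <- band_envelope(p$lfp, c(f / w, f * w), n_wavelets = n_wavelets,
                           reduce = "mean")
      m <- ts_valid_mask(env)
      stats::cor(p$vm$samples[m], env$samples[m])
    }, numeric(1))
  })
  cc_grid <- dplyr::mutate(cells, cc = vapply(cc_rec, mean, numeric(1)))
  best <- cc_grid[which.max(cc_grid$cc), ]
  out <- list(cc_grid = cc_grid, f_opt = best$f, w_opt = best$w,
              cc_opt = best$cc)

  if (!is.null(T_grid)) {
    if (!any(abs(T_grid) < 1e-12))
      stop("`T_grid` must contain 0 (the normalization reference)",
           call. = FALSE)
    curves <- purrr::imap(pairs, function(p, i) {
      env0 <- band_envelope(p$lfp, c(best$f / best$w, best$f * best$w),
                            n_wavelets = n_wavelets, reduce = "mean")
      m <- ts_valid_mask(env0)
      cc <- vapply(T_grid, function(Ts) {
        e <- if (Ts > 0) gaussian_smooth(env0, Ts) else env0
        stats::cor(p$vm$samples[m], e$samples[m])
      }, numeric(1))
      ncc <- cc / max(abs(cc))
      ncc <- ncc - ncc[which.min(abs(T_grid))]
      tibble::tibble(recording = i, T = as.numeric(T_grid), cc = cc,
                     ncc = ncc)
    })
    cc_vs_T <- dplyr::bind_rows(curves)
    mean_curve <- dplyr::summarise(dplyr::group_by(cc_vs_T, .data$T),
                                   ncc = mean(.data$ncc), .groups = "drop")
    out$cc_vs_T <- cc_vs_T
    out$T_opt <- mean_curve$T[which.max(mean_curve$ncc)]
  }
  structure(out, class = "nsi_band_search")
}

#' @export
print.nsi_band_search <- function(x, ...) {
  cat(sprintf("<nsi_band_search> f_opt = %.3g Hz, w_opt = %.3g (band [%.1f, %.1f] Hz), cc = %.3f\n",
              x$f_opt, x$w_opt, x$f_opt / x$w_opt, x$f_opt * x$w_opt,
              x$cc_opt))
  if (!is.null(x$T_opt))
    cat(sprintf("  T_opt = %.1f ms\n", 1e3 * x$T_opt))
  invisible(x)
}

#' Calibrate the rhythmicity factor alpha against a reference signal
#'
#' For each candidate alpha, network states are classified and validated on
#' the pLFP-based NSI, and the reference signal's delta-band envelope is
#' averaged over the episodes classified as rhythmic (per recording, then
#' across recordings). The resulting curve decays with alpha; it is fitted
#' with `A * exp(-alpha / lambda) + B` by nonlinear least squares and the
#' decay constant lambda is taken as the optimal alpha.
#'
#' @param pairs List of recordings, each a list with elements `plfp` (an
#'   `nsi_plfp` from [compute_plfp()]) and `reference` (an [timeseries()]:
#'   Vm in mV or a population rate in Hz, resampled/binned to the pLFP
#'   rate).
#' @param alpha_grid Candidate alpha values; should span at least
#'   `[0.5, 6]`.
#' @param params Base [nsi_params()]; `alpha` is overridden by the sweep.
#' @param min_episodes A recording contributes to the curve at a given alpha
#'   only when it holds more than this many rhythmic episodes there (the
#'   more-than-five rule for meaningful averages).
#' @return A list of class `nsi_alpha_calibration`: `curve` (tibble `alpha`,
#'   `mean_ref_delta_env`, `n_recordings`), `alpha_opt` (the fitted decay
#'   constant), `fit_coefs` (A, lambda, B) and the `nls` fit object.
#' @export
calibrate_alpha <- function(pairs, alpha_grid = seq(0.5, 6, by = 0.25),
                            params = nsi_params(), min_episodes = 5) {
  stopifnot(length(pairs) >= 1, length(alpha_grid) >= 3)
  alpha_grid <- sort(alpha_grid)

  per_rec <- purrr::map(pairs, function(p) {
    stopifnot(inherits(p$plfp, "nsi_plfp"), inherits(p$reference, "nsi_ts"))
    trace <- p$plfp$trace
    if (abs(p$reference$rate - trace$rate) > 1e-6)
      stop("reference must be at the pLFP trace rate", call. = FALSE)
    comp <- nsi_components(trace, params)
    ref_env <- band_envelope(p$reference, params$delta_band,
                             n_wavelets = params$n_delta_wavelets,
                             reduce = "max", d0 = params$d0)
    thr <- params$fluct_threshold
    if (is.null(thr)) thr <- p$plfp$p0
    list(comp = comp, ref_env = ref_env, p0 = p$plfp$p0, thr = thr)
  })

  # large-alpha limit of the curve: the mean reference delta envelope over
  # all validated episodes irrespective of label; fixes the offset B of the
  # exponential (a free 3-parameter fit is ill-conditioned on a slowly
  # decaying arc)
  B0 <- mean(vapply(per_rec, function(r) {
    nsi <- nsi_from_components(r$comp, r$p0, max(alpha_grid))
    ep <- validate_episodes_impl(nsi, params$T_state, r$thr)
    vv <- ep$t_center[ep$validated]
    if (length(vv) == 0L) return(NA_real_)
    i <- pmax(1L, pmin(length(r$ref_env$samples),
                       as.integer(round((vv - r$ref_env$t0) *
                                          r$ref_env$rate)) + 1L))
    mean(r$ref_env$samples[i])
  }, numeric(1)), na.rm = TRUE)

  curve <- purrr::map_dfr(alpha_grid, function(a) {
    per_rec_mean <- vapply(per_rec, function(r) {
      nsi <- nsi_from_components(r$comp, r$p0, a)
      ep <- validate_episodes_impl(nsi, params$T_state, r$thr)
      rhy <- ep$t_center[ep$validated & ep$label == "rhythmic"]
      if (length(rhy) <= min_episodes) return(NA_real_)
      i <- pmax(1L, pmin(length(r$ref_env$samples),
                         as.integer(round((rhy - r$ref_env$t0) *
                                            r$ref_env$rate)) + 1L))
      mean(r$ref_env$samples[i])
    }, numeric(1))
    tibble::tibble(alpha = a,
                   mean_ref_delta_env = mean(per_rec_mean, na.rm = TRUE),
                   n_recordings = sum(!is.na(per_rec_mean)))
  })
  if (all(is.nan(curve$mean_ref_delta_env) | curve$n_recordings == 0))
    stop("no rhythmic episodes at any alpha", call. = FALSE)
  cv <- dplyr::filter(curve, .data$n_recordings > 0)
  # the exponential decay is fitted from the curve's maximum onward: at very
  # small alpha the rhythmic set degenerates to near-silent episodes (the
  # oscillation trivially accounts for a near-baseline mean), which sit at
  # the contamination floor rather than on the decay
  i0 <- which.max(cv$mean_ref_delta_env)
  cv <- cv[i0:nrow(cv), ]
  if (nrow(cv) < 4L)
    stop("too few alpha points on the decaying branch to fit", call. = FALSE)
  if (cv$mean_ref_delta_env[nrow(cv)] >= cv$mean_ref_delta_env[1])
    stop("reference delta envelope does not decay with alpha; cannot fit",
         call. = FALSE)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      mean_ref_delta_env ~ A * exp(-alpha / lambda) + B0, data = cv,
      start = list(A = 2 * (max(cv$mean_ref_delta_env) -
                              min(cv$mean_ref_delta_env)),
                   lambda = stats::median(alpha_grid)),
      lower = c(A = 0, lambda = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exponential fit failed: ",
                             conditionMessage(e), call. = FALSE))
  co <- c(stats::coef(fit), B = B0)
  structure(list(curve = curve, alpha_opt = unname(co["lambda"]),
                 fit_coefs = co, fit = fit, alpha_grid = alpha_grid),
            class = "nsi_alpha_calibration")
}

#' @export
print.nsi_alpha_calibration <- function(x, ...) {
  cat(sprintf(
    "<nsi_alpha_calibration> alpha_opt = %.3g (A = %.3g, B = %.3g) over alpha in [%g, %g]\n",
    x$alpha_opt, x$fit_coefs["A"], x$fit_coefs["B"],
    min(x$alpha_grid), max(x$alpha_grid)))
  invisible(x)
}
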