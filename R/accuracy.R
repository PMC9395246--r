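#' Membrane-potential-based NSI
#'
#' Computes the NSI on a membrane-potential (Vm) trace with the same
#' machinery as the pLFP-based index: the noise floor is replaced by Vm0,
#' the first percentile of the Vm distribution, and episode validation uses
#' the Vm tolerance `vm_tol` (mV) as the fluctuation threshold. The Vm is
#' bin-averaged to 1-ms resolution first. This Vm-defined NSI is the
#' reference against which the LFP-defined index is cross-validated.
#'
#' @param vm Membrane potential [timeseries()] in mV at >= 1 kHz.
#' @param params An [nsi_params()] object (same parameters as for the pLFP).
#' @param vm0_percentile Percentile (in percent) defining Vm0.
#' @param vm_tol Episode-validation fluctuation threshold (mV, default 2).
#' @return An `nsi_trace` (see [compute_nsi()]) with `p0` holding Vm0.
#' @export
compute_vm_nsi <- function(vm, params = nsi_params(), vm0_percentile = 1,
                           vm_tol = 2) {
  stopifnot(inherits(vm, "nsi_ts"))
  if (vm$rate < 1000 - 1e-9)
    stop("Vm must be sampled at >= 1 kHz", call. = FALSE)
  if (vm$rate > 1000) vm <- ts_bin_average(vm, 0.001)
  vm0 <- estimate_p0(vm, vm0_percentile)
  params$fluct_threshold <- vm_tol
  compute_nsi(vm, params = params, p0 = vm0)
}

#' Pair pLFP- and Vm-based episodes on the common time grid
#'
#' Joins two episode tables (one per index) on their `T_state / 2` grid.
#'
#' @param ep_plfp,ep_vm Episode tables from [validate_episodes()] computed
#'   on the pLFP-based and Vm-based NSI of the same recording.
#' @return A tibble with columns `t_center`, `nsi_plfp`, `nsi_vm`,
#'   `validated_plfp`, `validated_vm`, `both_validated`.
#' @export
pair_episodes <- function(ep_plfp, ep_vm) {
  a <- tibble::tibble(key = round(ep_plfp$t_center * 1e6),
                      t_center = ep_plfp$t_center,
                      nsi_plfp = ep_plfp$nsi,
                      validated_plfp = ep_plfp$validated)
  b <- tibble::tibble(key = round(ep_vm$t_center * 1e6),
                      nsi_vm = ep_vm$nsi,
                      validated_vm = ep_vm$validated)
  dplyr::inner_join(a, b, by = "key") |>
    dplyr::mutate(both_validated = .data$validated_plfp &
                    .data$validated_vm) |>
    dplyr::select(-"key")
}

#' Fit the Vm-to-pLFP NSI scaling factor F
#'
#' Least-squares slope through the origin of `nsi_plfp ~ nsi_vm`, fitted
#' only on episodes where the two indices agree in sign (both rhythmic or
#' both nonrhythmic); discordant episodes are excluded from the fit. An
#' intercept variant is available but off by default, F being a scaling
#' factor.
#'
#' @param paired A [pair_episodes()] tibble (only rows validated in both
#'   indices are used).
#' @param intercept If TRUE fit `nsi_plfp ~ nsi_vm` with an intercept.
#' @return A list of class `nsi_scale_fit` with elements `F` (uV per mV),
#'   `intercept`, `n_fit`, `n_discordant`.
#' @export
fit_scale_factor <- function(paired, intercept = FALSE) {
  d <- dplyr::filter(paired, .data$both_validated)
  conc <- (d$nsi_vm <= 0) == (d$nsi_plfp <= 0)
  fit_d <- d[conc, ]
  if (nrow(fit_d) < 2L)
    stop("need at least two concordant-sign episode pairs", call. = FALSE)
  if (intercept) {
    m <- stats::lm(nsi_plfp ~ nsi_vm, data = fit_d)
    co <- stats::coef(m)
    out <- list(F = unname(co[2]), intercept = unname(co[1]))
  } else {
    out <- list(F = sum(fit_d$nsi_vm * fit_d$nsi_plfp) /
                  sum(fit_d$nsi_vm^2), intercept = 0)
  }
  out$n_fit <- nrow(fit_d)
  out$n_discordant <- sum(!conc)
  structure(out, class = "nsi_scale_fit")
}

#' @export
print.nsi_scale_fit <- function(x, ...) {
  cat(sprintf("<nsi_scale_fit> F = %.4g uV/mV (%d concordant pairs, %d discordant excluded)\n",
              x$F, x$n_fit, x$n_discordant))
  invisible(x)
}

misclass_category <- function(p, v) {
  dplyr::case_when(
    p > 0 & v <= 0 ~ "plfp>0 & vm<=0",
    p <= 0 & v > 0 ~ "plfp<=0 & vm>0",
    p > 0 & v > 0 ~ "plfp>0 & vm>0",
    TRUE ~ "plfp<=0 & vm<=0")
}

#' Tolerance-box accuracy of the pLFP-based NSI against the Vm-based NSI
#'
#' An episode is correctly detected iff the scaled prediction and the
#' observation agree within the joint tolerance box:
#' `F * (nsi_vm + vm_tol) > nsi_plfp - p_tol` and
#' `F * (nsi_vm - vm_tol) < nsi_plfp + p_tol`
#' (equivalently `|F * nsi_vm - nsi_plfp| < F * vm_tol + p_tol`). Accuracy
#' is the percentage of correct episodes over those validated in both
#' indices; episodes validated in only one index are reported separately and
#' not counted as errors. Misclassified episodes are split into the four
#' sign combinations of the two indices.
#'
#' @param paired A [pair_episodes()] tibble.
#' @param F Scaling factor from [fit_scale_factor()] (or an
#'   `nsi_scale_fit`).
#' @param p_tol pLFP-side tolerance (uV, default 2.85, the typical pLFP
#'   noise floor).
#' @param vm_tol Vm-side tolerance (mV, default 2).
#' @return A list of class `nsi_accuracy`: `accuracy` (percent), `F`,
#'   `p_tol`, `vm_tol`, `per_episode` (tibble with verdicts),
#'   `misclass_breakdown` (4-category tibble whose percentages sum to 100
#'   over misclassified episodes), `n_both`, `n_single_validated`.
#' @export
evaluate_accuracy <- function(paired, F, p_tol = 2.85, vm_tol = 2) {
  if (inherits(F, "nsi_scale_fit")) F <- F$F
  stopifnot(is.numeric(F), p_tol > 0, vm_tol > 0)
  if (nrow(paired) == 0L) stop("empty episode pairing", call. = FALSE)
  d <- dplyr::filter(paired, .data$both_validated)
  if (nrow(d) == 0L) stop("no jointly validated episodes", call. = FALSE)
  d <- dplyr::mutate(
    d,
    correct = F * (.data$nsi_vm + vm_tol) > .data$nsi_plfp - p_tol &
      F * (.data$nsi_vm - vm_tol) < .data$nsi_plfp + p_tol,
    category = dplyr::if_else(
      .data$correct, NA_character_,
      misclass_category(.data$nsi_plfp, .data$nsi_vm)))
  wrong <- dplyr::filter(d, !.data$correct)
  cats <- c("plfp>0 & vm<=0", "plfp<=0 & vm>0",
            "plfp>0 & vm>0", "plfp<=0 & vm<=0")
  counts <- vapply(cats, function(cc) sum(wrong$category == cc), integer(1))
  breakdown <- tibble::tibble(
    category = cats, n = as.integer(counts),
    percent = if (nrow(wrong) > 0) 100 * counts / nrow(wrong) else
      rep(NA_real_, 4L))
  structure(list(
    accuracy = 100 * mean(d$correct), F = F, p_tol = p_tol, vm_tol = vm_tol,
    per_episode = d, misclass_breakdown = breakdown,
    n_both = nrow(d),
    n_single_validated = sum(xor(paired$validated_plfp,
                                 paired$validated_vm))),
    class = "nsi_accuracy")
}

#' @export
print.nsi_accuracy <- function(x, ...) {
  cat(sprintf(
    "<nsi_accuracy> %.1f%% correct over %d jointly validated episodes\n",
    x$accuracy, x$n_both))
  cat(sprintf("  F = %.4g uV/mV, tolerances: %.3g uV / %.3g mV; %d episodes validated in one index only\n",
              x$F, x$p_tol, x$vm_tol, x$n_single_validated))
  print(x$misclass_breakdown)
  invisible(x)
}
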