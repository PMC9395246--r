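#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy / glance methods for fitted nsindex objects
#'
#' broom-style accessors: `tidy()` returns the per-observation or per-term
#' table of a result, `glance()` a one-row model summary.
#'
#' @param x A fitted object (`nsi_accuracy`, `nsi_alpha_calibration`,
#'   `nsi_band_search`, `nsi_regression`, `nsi_scale_fit`).
#' @param ... Unused.
#' @name nsindex-broom
NULL

#' @rdname nsindex-broom
#' @export
tidy.nsi_accuracy <- function(x, ...) x$per_episode

#' @rdname nsindex-broom
#' @export
glance.nsi_accuracy <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, F = x$F, p_tol = x$p_tol,
                 vm_tol = x$vm_tol, n_episodes = x$n_both,
                 n_single_validated = x$n_single_validated)
}

#' @rdname nsindex-broom
#' @export
tidy.nsi_alpha_calibration <- function(x, ...) x$curve

#' @rdname nsindex-broom
#' @export
glance.nsi_alpha_calibration <- function(x, ...) {
  tibble::tibble(alpha_opt = x$alpha_opt,
                 A = unname(x$fit_coefs["A"]),
                 B = unname(x$fit_coefs["B"]),
                 n_alpha = nrow(x$curve))
}

#' @rdname nsindex-broom
#' @export
tidy.nsi_band_search <- function(x, ...) x$cc_grid

#' @rdname nsindex-broom
#' @export
glance.nsi_band_search <- function(x, ...) {
  tibble::tibble(f_opt = x$f_opt, w_opt = x$w_opt, cc_opt = x$cc_opt,
                 T_opt = if (is.null(x$T_opt)) NA_real_ else x$T_opt)
}

#' @rdname nsindex-broom
#' @export
tidy.nsi_regression <- function(x, ...) x$univariate

#' @rdname nsindex-broom
#' @export
glance.nsi_regression <- function(x, ...) {
  tibble::tibble(adj_r2 = x$multiple$adj_r2, p = x$multiple$p,
                 best3_features = paste(x$best_subset$features,
                                        collapse = "+"),
                 best3_adj_r2 = x$best_subset$adj_r2,
                 best3_p = x$best_subset$p, n = x$n)
}

#' @rdname nsindex-broom
#' @export
glance.nsi_scale_fit <- function(x, ...) {
  tibble::tibble(F = x$F, intercept = x$intercept, n_fit = x$n_fit,
                 n_discordant = x$n_discordant)
}
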