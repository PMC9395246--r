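#' Plot methods
#'
#' `autoplot()` methods (ggplot2) for the package's result objects: the NSI
#' trace decomposition, validated episodes, the band-search correlation
#' grid, the alpha-calibration decay curve and the accuracy scatter.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name nsindex-autoplot
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname nsindex-autoplot
#' @param max_points Traces are thinned to at most this many points per
#'   panel before plotting.
#' @export
autoplot.nsi_trace <- function(object, max_points = 20000, ...) {
  thin <- function(ts, lab) {
    d <- as_tibble(ts)
    if (nrow(d) > max_points)
      d <- d[seq(1, nrow(d), length.out = max_points), ]
    d$signal <- lab
    d
  }
  d <- dplyr::bind_rows(thin(object$x, "X = p0 + alpha.delta_env"),
                        thin(object$y, "Y (sliding mean)"),
                        thin(object$nsi, "NSI"))
  d$signal <- factor(d$signal, levels = unique(d$signal))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(data = data.frame(signal = factor("NSI"),
                                          y0 = 0),
                        ggplot2::aes(yintercept = .data$y0),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = object$units)
}

#' @rdname nsindex-autoplot
#' @export
autoplot.nsi_episodes <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(dplyr::filter(d, .data$validated),
                  ggplot2::aes(x = .data$t_center, y = .data$nsi,
                               colour = .data$label)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(rhythmic = "#7b3294",
                                            nonrhythmic = "#7f6000")) +
    ggplot2::labs(x = "time (s)",
                  y = paste0("NSI (", attr(object, "units") %||% "uV", ")"),
                  colour = NULL)
}

#' @rdname nsindex-autoplot
#' @export
autoplot.nsi_band_search <- function(object, ...) {
  ggplot2::ggplot(object$cc_grid,
                  ggplot2::aes(x = factor(round(.data$f, 2)),
                               y = factor(round(.data$w, 3)),
                               fill = .data$cc)) +
    ggplot2::geom_tile() +
    ggplot2::annotate("point", x = factor(round(object$f_opt, 2)),
                      y = factor(round(object$w_opt, 3)), shape = 21,
                      size = 4, colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "root frequency f (Hz)", y = "width factor w",
                  fill = "cc(Vm, env)")
}

#' @rdname nsindex-autoplot
#' @export
autoplot.nsi_alpha_calibration <- function(object, ...) {
  cv <- dplyr::filter(object$curve, .data$n_recordings > 0)
  co <- object$fit_coefs
  cv$fitted <- co["A"] * exp(-cv$alpha / co["lambda"]) + co["B"]
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$alpha)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_ref_delta_env)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red",
                       linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$alpha_opt,
                        linetype = "dotted") +
    ggplot2::labs(x = "alpha", y = "mean reference delta envelope",
                  subtitle = sprintf("alpha_opt = %.2f", object$alpha_opt))
}

#' @rdname nsindex-autoplot
#' @export
autoplot.nsi_accuracy <- function(object, ...) {
  d <- object$per_episode
  ggplot2::ggplot(d, ggplot2::aes(x = .data$nsi_vm, y = .data$nsi_plfp,
                                  colour = .data$correct)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_abline(slope = object$F, intercept = 0,
                         linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2c7a2c",
                                            `FALSE` = "#c23b3b")) +
    ggplot2::labs(x = "NSI (Vm, mV)", y = "NSI (pLFP, uV)",
                  colour = "correct",
                  subtitle = sprintf("accuracy %.1f%% (F = %.2f uV/mV)",
                                     object$accuracy, object$F))
}
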