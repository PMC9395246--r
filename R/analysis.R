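#' Bin episode-level values by NSI level
#'
#' Standardizes per-episode quantities (e.g. mean Vm depolarization, MUA)
#' across recordings by binning the NSI axis (1-uV bins by default) and
#' reporting the per-bin mean and standard error. Bins holding `min_count`
#' or fewer episodes are suppressed (only levels with more than five
#' validated episodes give a meaningful average).
#'
#' @param data A data frame of per-episode records.
#' @param value Column holding the quantity to average (tidy-eval).
#' @param nsi Column holding the episode NSI level (tidy-eval, default
#'   `nsi`).
#' @param bin_width Bin width in NSI units (uV), default 1.
#' @param min_count Minimum episode count; bins with `n <= min_count` are
#'   dropped (default 5).
#' @return A tibble with columns `nsi_bin` (bin center), `mean`, `sem`, `n`.
#' @examples
#' df <- tibble::tibble(nsi = runif(200, 0, 10), vm = -70 + 1.5 * nsi)
#' bin_by_nsi(df, vm)
#' @export
bin_by_nsi <- function(data, value, nsi = nsi, bin_width = 1, min_count = 5) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  x <- rlang::eval_tidy(rlang::enquo(nsi), data)
  if (length(v) != length(x))
    stop("`value` and `nsi` must have equal length", call. = FALSE)
  keep <- !is.na(v) & !is.na(x)
  v <- v[keep]; x <- x[keep]
  ctr <- (floor(x / bin_width) + 0.5) * bin_width
  tibble::tibble(nsi_bin = ctr, value = v) |>
    dplyr::group_by(.data$nsi_bin) |>
    dplyr::summarise(mean = mean(.data$value),
                     sem = stats::sd(.data$value) /
                       sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n > min_count) |>
    dplyr::arrange(.data$nsi_bin)
}

#' Mean of a signal over each episode's state window
#'
#' For relating episode NSI levels to a simultaneous signal (membrane
#' potential depolarization, MUA, population rate): averages the signal over
#' the `T_state` window centered on each episode.
#'
#' @param x An [timeseries()] simultaneous with the episodes.
#' @param episodes An [validate_episodes()] table.
#' @param T_state Window duration (s); defaults to the table's own state
#'   window when available, else 0.4.
#' @return Numeric vector, one mean per episode row (NA where the window
#'   falls outside the trace).
#' @export
episode_window_means <- function(x, episodes, T_state = NULL) {
  stopifnot(inherits(x, "nsi_ts"))
  if (is.null(T_state)) {
    p <- attr(episodes, "params")
    T_state <- if (!is.null(p)) p$T_state else 0.4
  }
  half <- T_state / 2
  n <- length(x$samples)
  vapply(episodes$t_center, function(tc) {
    lo <- as.integer(round((tc - half - x$t0) * x$rate)) + 1L
    hi <- as.integer(round((tc + half - x$t0) * x$rate)) + 1L
    if (lo < 1L || hi > n) return(NA_real_)
    mean(x$samples[lo:hi])
  }, numeric(1))
}

#' Distribution features of a recording's NSI episodes
#'
#' The seven summary statistics of the per-recording NSI distribution used
#' to explain across-recording variability of the Vm-pLFP coupling:
#' mean and SD over all validated episodes (`mu_NSI`, `sigma_NSI`), the
#' fraction of rhythmic episodes (`F_rhythmic`, NSI <= 0), and mean/SD
#' restricted to each sign class (`mu_pos`, `mu_neg`, `sigma_pos`,
#' `sigma_neg`; NA when the class is empty or a singleton for SDs).
#'
#' @param episodes An [validate_episodes()] table with at least one
#'   validated episode.
#' @return A one-row tibble (plus `recording_id` when the table carries
#'   one).
#' @export
distribution_features <- function(episodes) {
  v <- episodes$nsi[episodes$validated]
  if (length(v) == 0L) stop("no validated episodes", call. = FALSE)
  pos <- v[v > 0]; neg <- v[v <= 0]
  sd_or_na <- function(z) if (length(z) >= 2L) stats::sd(z) else NA_real_
  mean_or_na <- function(z) if (length(z) >= 1L) mean(z) else NA_real_
  out <- tibble::tibble(
    mu_NSI = mean(v), sigma_NSI = sd_or_na(v),
    F_rhythmic = length(neg) / length(v),
    mu_pos = mean_or_na(pos), mu_neg = mean_or_na(neg),
    sigma_pos = sd_or_na(pos), sigma_neg = sd_or_na(neg))
  id <- attr(episodes, "recording_id")
  if (!is.null(id)) out <- dplyr::mutate(out, recording_id = id,
                                         .before = 1)
  out
}

nsi_feature_names <- c("mu_NSI", "sigma_NSI", "F_rhythmic", "mu_pos",
                       "mu_neg", "sigma_pos", "sigma_neg")

adj_r2 <- function(m) summary(m)$adj.r.squared
f_test_p <- function(m) {
  fs <- summary(m)$fstatistic
  if (is.null(fs)) return(NA_real_)
  unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
}

#' Regress the Vm-pLFP correlation on NSI-distribution features
#'
#' Ordinary least-squares univariate fits of the per-recording coupling
#' `cc` on each distribution feature, a full multiple regression on all
#' features, and the best three-feature subset by adjusted R^2 (exhaustive
#' enumeration over the 35 triples). Explained variances are adjusted for
#' the number of linear factors; model significance is the overall F test.
#'
#' @param records A data frame with one row per recording holding the
#'   feature columns (see [distribution_features()]) and the response.
#' @param response Name of the response column (default `"cc"`).
#' @param features Feature column names (default the seven NSI-distribution
#'   features).
#' @return A list of class `nsi_regression`: `univariate` (tibble `feature`,
#'   `adj_r2`, `p`), `multiple` (list `adj_r2`, `p`, `model`),
#'   `best_subset` (list `features`, `adj_r2`, `p`, `model`).
#' @export
regress_cc_on_features <- function(records, response = "cc",
                                   features = nsi_feature_names) {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(c(response, features), names(records))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  full <- stats::na.omit(records[, c(response, features)])
  if (nrow(full) < length(features) + 3L)
    stop("need at least 3 more complete records than features",
         call. = FALSE)
  X <- as.matrix(full[, features])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    drop_idx <- setdiff(seq_len(ncol(X) + 1L), qrX$pivot[seq_len(qrX$rank)])
    stop("rank-deficient design; collinear feature(s): ",
         paste(features[drop_idx - 1L], collapse = ", "), call. = FALSE)
  }

  uni <- purrr::map_dfr(features, function(f) {
    d <- stats::na.omit(records[, c(response, f)])
    m <- stats::lm(stats::reformulate(f, response), data = d)
    tibble::tibble(feature = f, adj_r2 = adj_r2(m), p = f_test_p(m),
                   n = nrow(d))
  }) |> dplyr::arrange(dplyr::desc(.data$adj_r2))

  m_full <- stats::lm(stats::reformulate(features, response), data = full)

  triples <- utils::combn(features, 3L, simplify = FALSE)
  fits <- purrr::map(triples, function(tr)
    stats::lm(stats::reformulate(tr, response), data = full))
  best_i <- which.max(vapply(fits, adj_r2, numeric(1)))

  structure(list(
    univariate = uni,
    multiple = list(adj_r2 = adj_r2(m_full), p = f_test_p(m_full),
                    model = m_full),
    best_subset = list(features = triples[[best_i]],
                       adj_r2 = adj_r2(fits[[best_i]]),
                       p = f_test_p(fits[[best_i]]),
                       model = fits[[best_i]]),
    response = response, n = nrow(full)),
    class = "nsi_regression")
}

#' @export
print.nsi_regression <- function(x, ...) {
  cat(sprintf("<nsi_regression> %s ~ NSI-distribution features (n = %d)\n",
              x$response, x$n))
  cat(sprintf("  full model: adj R2 = %.3f (F-test p = %.3g)\n",
              x$multiple$adj_r2, x$multiple$p))
  cat(sprintf("  best 3-feature subset [%s]: adj R2 = %.3f (p = %.3g)\n",
              paste(x$best_subset$features, collapse = ", "),
              x$best_subset$adj_r2, x$best_subset$p))
  print(x$univariate)
  invisible(x)
}

#' Gamma-to-delta envelope ratio of an LFP
#'
#' The classical baseline state index: the per-sample ratio of the gamma
#' band envelope (default [30, 80] Hz) to the delta band envelope
#' (default [2, 4] Hz), each the mean of 20 wavelet envelopes. Samples with
#' a zero delta envelope are flagged missing.
#'
#' @param lfp An [timeseries()] with rate >= twice the gamma band's upper
#'   edge.
#' @param gamma_band,delta_band Frequency bands in Hz.
#' @param n_wavelets Wavelets per band.
#' @return An [timeseries()] (dimensionless) with NA at zero-delta samples.
#' @export
gamma_delta_ratio <- function(lfp, gamma_band = c(30, 80),
                              delta_band = c(2, 4), n_wavelets = 20) {
  stopifnot(inherits(lfp, "nsi_ts"))
  if (lfp$rate < 2 * gamma_band[2])
    stop(sprintf("rate %g Hz below Nyquist for the %g Hz gamma edge",
                 lfp$rate, gamma_band[2]), call. = FALSE)
  ge <- band_envelope(lfp, gamma_band, n_wavelets, reduce = "mean")
  de <- band_envelope(lfp, delta_band, n_wavelets, reduce = "mean")
  ratio <- ifelse(de$samples > 0, ge$samples / de$samples, NA_real_)
  # may contain NA at zero-delta samples, so bypass the finite check
  ts_like(lfp, samples = ratio, units = "ratio",
          edge = max(ge$edge, de$edge))
}

#' Select the LFP channel with the strongest delta-range pLFP envelope
#'
#' For multi-channel probes (e.g. Neuropixels in V1): computes the pLFP of
#' every channel and returns the channel whose session-mean delta-band pLFP
#' envelope is largest.
#'
#' @param channels List of LFP [timeseries()] objects.
#' @param params A [plfp_params()].
#' @param delta_band Delta band in Hz (the V1 preset uses [4, 8]).
#' @return A list with `index` (selected channel) and `scores` (mean delta
#'   envelope per channel, uV).
#' @export
select_delta_channel <- function(channels, params = plfp_params(),
                                 delta_band = c(2, 4)) {
  stopifnot(length(channels) >= 1)
  scores <- vapply(channels, function(ch) {
    pl <- compute_plfp(ch, params)
    de <- band_envelope(pl$trace, delta_band, n_wavelets = 20,
                        reduce = "max")
    mean(de$samples[ts_valid_mask(de)])
  }, numeric(1))
  list(index = which.max(scores), scores = scores)
}

#' Population firing rate from pooled spike times
#'
#' Pools spikes over units, bins them (5-ms bins) and applies a 30-ms
#' Gaussian smoothing, yielding a rate trace in Hz. With no spikes a
#' zero-rate trace is returned with a warning.
#'
#' @param spikes Numeric vector of spike times (s), or a list of per-unit
#'   spike-time vectors to pool.
#' @param t_start,t_end Span of the recording (s).
#' @param bin Bin width (s), default 5 ms.
#' @param smooth Gaussian smoothing width (s), default 30 ms.
#' @return An [timeseries()] in Hz at `1 / bin` resolution.
#' @export
population_rate <- function(spikes, t_start, t_end, bin = 0.005,
                            smooth = 0.03) {
  if (is.list(spikes)) spikes <- unlist(spikes, use.names = FALSE)
  spikes <- spikes[spikes >= t_start & spikes <= t_end]
  edges <- seq(t_start, t_end, by = bin)
  if (length(edges) < 2L) stop("span shorter than one bin", call. = FALSE)
  if (length(spikes) == 0L) {
    warning("no spikes in span: zero-rate trace", call. = FALSE)
    counts <- numeric(length(edges) - 1L)
  } else {
    counts <- graphics::hist(spikes, breaks = edges, plot = FALSE)$counts
  }
  rate <- timeseries(counts / bin, rate = 1 / bin,
                     t0 = t_start + bin / 2, units = "Hz")
  if (smooth > 0) rate <- gaussian_smooth(rate, smooth)
  rate
}
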