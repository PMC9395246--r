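#' Parameters of the Network State Index
#'
#' Defaults are the calibrated S1 values: rhythmicity factor alpha = 2.87,
#' sliding-mean window T_mean = 500 ms, delta band [2, 4] Hz sampled by 20
#' wavelets, state window T_state = 400 ms, and an episode-validation
#' fluctuation threshold equal to the recording's own pLFP noise floor p0.
#' The visual-cortex preset ([preset_v1()]) shifts the delta band to
#' [4, 8] Hz with alpha = 3.07.
#'
#' @param alpha Rhythmicity factor (> 0) weighting the delta envelope in the
#'   rhythmic/nonrhythmic criterion.
#' @param T_mean Sliding-mean Gaussian time constant (s).
#' @param delta_band Length-2 numeric, the delta band in Hz.
#' @param n_delta_wavelets Wavelets sampling the delta band.
#' @param T_state Episode window duration (s); episodes step by `T_state/2`.
#' @param fluct_threshold Episode-validation fluctuation threshold in signal
#'   units; `NULL` (default) means "use the trace's own noise floor p0".
#' @param d0 Wavelet decay parameter.
#' @return A list of class `nsi_params`.
#' @export
nsi_params <- function(alpha = 2.87, T_mean = 0.5, delta_band = c(2, 4),
                       n_delta_wavelets = 20, T_state = 0.4,
                       fluct_threshold = NULL, d0 = 6) {
  stopifnot(alpha > 0, T_mean >= 0, T_state > 0,
            length(delta_band) == 2L, delta_band[1] > 0,
            delta_band[2] >= delta_band[1], n_delta_wavelets >= 1)
  structure(list(alpha = alpha, T_mean = T_mean, delta_band = delta_band,
                 n_delta_wavelets = n_delta_wavelets, T_state = T_state,
                 fluct_threshold = fluct_threshold, d0 = d0),
            class = "nsi_params")
}

# delta envelope (max-reduce) and sliding mean of a 1-kHz trace; shared by
# compute_nsi() and the alpha calibration sweep
nsi_components <- function(trace, params) {
  if (params$delta_band[2] > trace$rate / 2)
    stop("delta band above the trace's Nyquist frequency", call. = FALSE)
  delta_env <- band_envelope(trace, params$delta_band,
                             n_wavelets = params$n_delta_wavelets,
                             reduce = "max", d0 = params$d0)
  y <- gaussian_smooth(trace, params$T_mean)
  list(delta_env = delta_env, y = y)
}

nsi_from_components <- function(comp, p0, alpha) {
  x_samp <- p0 + alpha * comp$delta_env$samples
  y_samp <- comp$y$samples
  rhythmic <- x_samp >= y_samp   # ties go to the rhythmic branch
  nsi <- ifelse(rhythmic, -2 * comp$delta_env$samples, y_samp - p0)
  ts_like(comp$delta_env, samples = nsi,
          edge = max(comp$delta_env$edge, comp$y$edge))
}

#' Compute the time-varying Network State Index (NSI)
#'
#' From a pLFP trace (or, via [compute_vm_nsi()], a membrane-potential
#' trace) derives: the delta-band envelope `delta_env` (maximum over 20
#' wavelets spanning the delta band), the sliding mean `Y` (Gaussian, time
#' constant `T_mean`), the rhythmicity estimate `X = p0 + alpha * delta_env`,
#' and the signed index
#' \deqn{NSI(t) = -2\,\delta_{env}\,H(X - Y) + (Y - p_0)\,H(Y - X)}
#' where H is the Heaviside step (ties `X = Y` are rhythmic). Negative NSI
#' magnitude is the delta-oscillation amplitude; positive NSI is the
#' baseline-subtracted mean activity level.
#'
#' @param plfp An `nsi_plfp` object from [compute_plfp()], or an
#'   [timeseries()] plus an explicit `p0`.
#' @param params An [nsi_params()] object.
#' @param p0 Noise floor; taken from `plfp$p0` when `plfp` is an `nsi_plfp`.
#' @return A list of class `nsi_trace` with [timeseries()] elements
#'   `delta_env`, `x`, `y`, `nsi`, plus `p0` and `params`.
#' @export
compute_nsi <- function(plfp, params = nsi_params(), p0 = NULL) {
  if (inherits(plfp, "nsi_plfp")) {
    trace <- plfp$trace
    if (is.null(p0)) p0 <- plfp$p0
  } else if (inherits(plfp, "nsi_ts")) {
    trace <- plfp
    if (is.null(p0)) stop("`p0` required when passing a bare trace",
                          call. = FALSE)
  } else stop("`plfp` must be an nsi_plfp or nsi_ts object", call. = FALSE)
  stopifnot(inherits(params, "nsi_params"))
  comp <- nsi_components(trace, params)
  nsi <- nsi_from_components(comp, p0, params$alpha)
  x <- ts_like(comp$delta_env,
               samples = p0 + params$alpha * comp$delta_env$samples)
  structure(list(delta_env = comp$delta_env, x = x, y = comp$y, nsi = nsi,
                 p0 = p0, params = params, units = trace$units),
            class = "nsi_trace")
}

#' @export
print.nsi_trace <- function(x, ...) {
  cat(sprintf(
    "<nsi_trace> alpha = %.3g, delta band [%g, %g] Hz, p0 = %.3g %s\n",
    x$params$alpha, x$params$delta_band[1], x$params$delta_band[2],
    x$p0, x$units))
  print(x$nsi)
  invisible(x)
}

# episode grid centers and window sample indices for a trace
episode_grid <- function(trace, T_state) {
  half <- T_state / 2
  t_end <- trace$t0 + ts_duration(trace)
  centers <- seq(trace$t0 + half, t_end, by = half)
  centers[centers + half <= t_end + 1e-9]
}

validate_episodes_impl <- function(nsi_ts_obj, T_state, threshold,
                                   value = c("center", "window_mean")) {
  value <- match.arg(value)
  half <- T_state / 2
  centers <- episode_grid(nsi_ts_obj, T_state)
  if (length(centers) == 0L) {
    warning("trace shorter than T_state: no episodes", call. = FALSE)
    return(tibble::tibble(t_center = numeric(), nsi = numeric(),
                          label = character(), validated = logical()))
  }
  s <- nsi_ts_obj$samples
  r <- nsi_ts_obj$rate
  n <- length(s)
  lo <- pmax(1L, as.integer(round((centers - half - nsi_ts_obj$t0) * r)) + 1L)
  hi <- pmin(n, as.integer(round((centers + half - nsi_ts_obj$t0) * r)) + 1L)
  ctr <- pmin(n, pmax(1L, as.integer(round((centers - nsi_ts_obj$t0) * r)) + 1L))
  # windows overlapping the filter-transient margins are not classifiable
  edge_n <- ceiling(nsi_ts_obj$edge * r)
  in_body <- (lo > edge_n) & (hi <= n - edge_n)
  ok <- logical(length(centers))
  val <- rep(NA_real_, length(centers))
  for (i in seq_along(centers)) {
    if (!in_body[i]) next
    w <- s[lo[i]:hi[i]]
    if (max(w) - min(w) <= threshold) {
      ok[i] <- TRUE
      val[i] <- if (value == "center") s[ctr[i]] else mean(w)
    }
  }
  tibble::tibble(
    t_center = centers,
    nsi = val,
    label = dplyr::case_when(!ok ~ "unclassified",
                             val <= 0 ~ "rhythmic",
                             TRUE ~ "nonrhythmic"),
    validated = ok
  )
}

#' Validate stable network-state episodes
#'
#' Walks the time axis in steps of `T_state / 2` and, for each grid point,
#' validates the surrounding `T_state` window as a well-defined network
#' state iff the NSI fluctuation (max - min) within the window does not
#' exceed the fluctuation threshold (the noise floor p0 by default).
#' Windows extending past either end of the recording, or overlapping the
#' edge-flagged filter-transient margins, are unclassified. A validated
#' episode is rhythmic iff its NSI value is <= 0.
#'
#' @param nsi An `nsi_trace` from [compute_nsi()] or [compute_vm_nsi()].
#' @param value How to summarise the episode's NSI: the window's center
#'   sample (default) or the window mean.
#' @param recording_id Optional label stored on the table.
#' @return A tibble of class `nsi_episodes` with columns `t_center` (s),
#'   `nsi` (trace units; NA when unclassified), `label`
#'   (rhythmic / nonrhythmic / unclassified) and `validated` (logical).
#' @export
validate_episodes <- function(nsi, value = c("center", "window_mean"),
                              recording_id = NULL) {
  stopifnot(inherits(nsi, "nsi_trace"))
  thr <- nsi$params$fluct_threshold
  if (is.null(thr)) thr <- nsi$p0
  tbl <- validate_episodes_impl(nsi$nsi, nsi$params$T_state, thr, value)
  attr(tbl, "units") <- nsi$units
  attr(tbl, "p0") <- nsi$p0
  attr(tbl, "params") <- nsi$params
  attr(tbl, "recording_id") <- recording_id
  class(tbl) <- c("nsi_episodes", class(tbl))
  tbl
}

#' Fractions of rhythmic, nonrhythmic and unclassified episodes
#'
#' @param episodes An [validate_episodes()] table.
#' @return A tibble with columns `label`, `n` and `percent`; the three
#'   percentages sum to 100.
#' @export
state_fractions <- function(episodes) {
  if (nrow(episodes) == 0L) stop("empty episode table", call. = FALSE)
  labels <- c("rhythmic", "nonrhythmic", "unclassified")
  n <- vapply(labels, function(l) sum(episodes$label == l), integer(1))
  tibble::tibble(label = labels, n = as.integer(n),
                 percent = 100 * n / sum(n))
}
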