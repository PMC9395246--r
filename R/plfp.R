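#' Parameters of the processed-LFP (pLFP) transform
#'
#' Defaults are the calibrated values for awake mouse S1: root frequency
#' f0 = 72.8 Hz and width factor w0 = 1.83 (i.e. the ~[39.8, 133.2] Hz
#' high-gamma band), 5 wavelets, Gaussian smoothing of 42.2 ms, and
#' downsampling to 1-ms bins. The noise floor p0 is the 1st percentile of
#' the pLFP amplitude distribution.
#'
#' @param f0 Root frequency (Hz).
#' @param w0 Band width factor (>= 1); the band is `[f0/w0, f0*w0]`.
#' @param n_wavelets Number of wavelets spanning the band.
#' @param T_smoothing Gaussian smoothing standard deviation (s).
#' @param d0 Wavelet decay parameter.
#' @param downsample_bin Bin-averaging resolution (s), default 1 ms.
#' @param p0_percentile Percentile (in percent, within (0, 50)) defining the
#'   noise floor p0.
#' @return A list of class `plfp_params`.
#' @export
plfp_params <- function(f0 = 72.8, w0 = 1.83, n_wavelets = 5,
                        T_smoothing = 0.0422, d0 = 6,
                        downsample_bin = 0.001, p0_percentile = 1) {
  stopifnot(f0 > 0, w0 >= 1, n_wavelets >= 1, T_smoothing >= 0, d0 > 0,
            downsample_bin > 0)
  if (p0_percentile <= 0 || p0_percentile >= 50)
    stop("`p0_percentile` must lie in (0, 50)", call. = FALSE)
  structure(list(f0 = f0, w0 = w0, n_wavelets = n_wavelets,
                 T_smoothing = T_smoothing, d0 = d0,
                 downsample_bin = downsample_bin,
                 p0_percentile = p0_percentile),
            class = "plfp_params")
}

#' Noise floor of a pLFP trace
#'
#' The stated (low) percentile of the amplitude distribution over the whole
#' recording, with linear interpolation between order statistics
#' (type-7 quantiles). Interpreted as the residual high-gamma envelope in
#' the absence of neural activity.
#'
#' @param x An [timeseries()] (a pLFP trace) or numeric vector.
#' @param percentile Percentile in percent (default 1).
#' @return A single numeric value in the trace's units.
#' @export
estimate_p0 <- function(x, percentile = 1) {
  v <- if (inherits(x, "nsi_ts")) x$samples else as.numeric(x)
  if (length(v) < 1L) stop("empty trace", call. = FALSE)
  unname(stats::quantile(v, probs = percentile / 100, type = 7, names = FALSE))
}

#' Compute the processed LFP (pLFP)
#'
#' Transforms a raw LFP into its temporally smoothed high-gamma envelope:
#' the mean of `n_wavelets` Morlet wavelet envelopes evenly spanning
#' `[f0/w0, f0*w0]`, Gaussian-smoothed with `T_smoothing`, then bin-averaged
#' down to `downsample_bin` resolution (1 kHz by default). The noise floor
#' p0 is the `p0_percentile` percentile of the resulting trace.
#'
#' @param lfp Raw LFP [timeseries()] in uV; rate must be at least
#'   `2 * f0 * w0`.
#' @param params A [plfp_params()] object.
#' @return A list of class `nsi_plfp` with elements `trace` (an
#'   [timeseries()] at `1/downsample_bin` Hz), `p0` (uV) and `params`.
#' @examples
#' \donttest{
#' rec <- generate_recording(synth_config(duration = 20, fs = 2000, seed = 1))
#' p <- compute_plfp(rec$lfp, plfp_params())
#' p$p0
#' }
#' @export
compute_plfp <- function(lfp, params = plfp_params()) {
  stopifnot(inherits(lfp, "nsi_ts"), inherits(params, "plfp_params"))
  f_hi <- params$f0 * params$w0
  f_lo <- params$f0 / params$w0
  if (lfp$rate < 2 * f_hi)
    stop(sprintf("LFP rate %g Hz below Nyquist for the %g Hz band edge",
                 lfp$rate, f_hi), call. = FALSE)
  if (ts_duration(lfp) <= 2 * wavelet_window(f_lo, params$d0))
    stop("recording shorter than twice the widest wavelet window",
         call. = FALSE)
  env <- band_envelope(lfp, c(f_lo, f_hi), n_wavelets = params$n_wavelets,
                       reduce = "mean", d0 = params$d0)
  env <- gaussian_smooth(env, params$T_smoothing)
  if (params$downsample_bin * lfp$rate > 1 + 1e-9)
    env <- ts_bin_average(env, params$downsample_bin)
  p0 <- estimate_p0(env, params$p0_percentile)
  structure(list(trace = env, p0 = p0, params = params), class = "nsi_plfp")
}

#' @export
print.nsi_plfp <- function(x, ...) {
  cat(sprintf(
    "<nsi_plfp> band [%.1f, %.1f] Hz, smoothing %.1f ms, p0 = %.3g %s\n",
    x$params$f0 / x$params$w0, x$params$f0 * x$params$w0,
    1e3 * x$params$T_smoothing, x$p0, x$trace$units))
  print(x$trace)
  invisible(x)
}
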