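#' Uniformly sampled time series
#'
#' The universal signal carrier of the package: a numeric vector of samples
#' together with its sampling rate, start time and a unit label. LFP and
#' pLFP traces are conventionally in microvolts (uV), membrane potential in
#' millivolts (mV), population rates in Hz.
#'
#' @param samples Numeric vector of finite sample values (length >= 1).
#' @param rate Sampling rate in Hz (> 0).
#' @param t0 Start time of the first sample, in seconds.
#' @param units Unit label for the samples (e.g. "uV", "mV", "Hz").
#' @param edge Duration (s) at each end of the trace considered contaminated
#'   by filter onset transients; downstream averages exclude it.
#'
#' @return An object of class `nsi_ts`.
#' @examples
#' x <- timeseries(sin(2 * pi * 3 * seq(0, 1, by = 1e-3)), rate = 1000)
#' x
#' @export
timeseries <- function(samples, rate, t0 = 0, units = "uV", edge = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("`samples` must have length >= 1", call. = FALSE)
  if (!all(is.finite(samples))) stop("`samples` must be finite", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)", call. = FALSE)
  structure(
    list(samples = samples, rate = rate, t0 = t0,
         units = units, edge = edge),
    class = "nsi_ts"
  )
}

#' @export
print.nsi_ts <- function(x, ...) {
  cat(sprintf("<nsi_ts> %d samples @ %g Hz (%.3f s), units: %s\n",
              length(x$samples), x$rate, ts_duration(x), x$units))
  if (x$edge > 0) cat(sprintf("  edge-flagged: %.3f s at each end\n", x$edge))
  invisible(x)
}

#' @export
length.nsi_ts <- function(x) length(x$samples)

#' Time axis of a time series
#' @param x An `nsi_ts`.
#' @return Numeric vector of sample times in seconds.
#' @export
ts_times <- function(x) x$t0 + (seq_along(x$samples) - 1) / x$rate

#' Duration of a time series in seconds
#' @param x An `nsi_ts`.
#' @export
ts_duration <- function(x) (length(x$samples) - 1) / x$rate

#' Logical mask of samples outside the edge-flagged margins
#' @param x An `nsi_ts`.
#' @param edge Margin in seconds; defaults to the trace's own edge flag.
#' @export
ts_valid_mask <- function(x, edge = x$edge) {
  n <- length(x$samples)
  k <- min(n, ceiling(edge * x$rate))
  mask <- rep(TRUE, n)
  if (k > 0) {
    mask[seq_len(k)] <- FALSE
    mask[seq.int(n - k + 1L, n)] <- FALSE
  }
  mask
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.nsi_ts <- function(x, ...) {
  tibble::tibble(t = ts_times(x), value = x$samples)
}

#' @export
as.data.frame.nsi_ts <- function(x, ...) as.data.frame(as_tibble(x))

ts_like <- function(template, samples, ...) {
  out <- template
  out$samples <- as.numeric(samples)
  dots <- list(...)
  for (nm in names(dots)) out[[nm]] <- dots[[nm]]
  out
}

#' Downsample a time series by bin-averaging
#'
#' Averages consecutive non-overlapping bins of duration `bin` seconds.
#' Bins start at `t0`; a final partial bin is dropped. The returned trace is
#' stamped at the bin centers' grid origin (t0 shifted by half a bin).
#'
#' @param x An `nsi_ts`.
#' @param bin Bin duration in seconds; must hold an integer number >= 1 of
#'   input samples.
#' @return An `nsi_ts` at rate `1/bin`.
#' @export
ts_bin_average <- function(x, bin) {
  k <- bin * x$rate
  if (abs(k - round(k)) > 1e-6)
    stop("bin duration must be an integer multiple of the sampling interval",
         call. = FALSE)
  k <- as.integer(round(k))
  if (k < 1L) stop("bin shorter than one sample", call. = FALSE)
  n_bins <- length(x$samples) %/% k
  if (n_bins < 1L) stop("trace shorter than one bin", call. = FALSE)
  m <- matrix(x$samples[seq_len(n_bins * k)], nrow = k)
  ts_like(x, samples = colMeans(m), rate = x$rate / k,
          t0 = x$t0 + (k - 1) / (2 * x$rate))
}
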