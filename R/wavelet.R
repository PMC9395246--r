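#' Morlet wavelet envelope machinery
#'
#' The package's spectral estimates are all built on a Morlet wavelet
#' transform
#' \deqn{M_{d_0}(f, t) = C_{d_0}(f)\, e^{2 i \pi f t}\, e^{-(2 \pi f t / d_0)^2}}
#' convolved (complex conjugated) against the locally mean-subtracted signal
#' over a finite window. The window half-width is the extent at which the
#' Gaussian envelope has decayed by 1 - e^{-4} = 98.2 percent,
#' \eqn{T_f = 2 d_0 / (\pi f)}. The decay parameter defaults to d0 = 6.
#'
#' Normalization is with respect to a sinusoid, not the wavelet itself: the
#' coefficient C_{d_0}(f) is fixed so that a unit-amplitude sinusoid at the
#' wavelet frequency yields an envelope of exactly 1. C is evaluated
#' numerically on the working sampling grid (the printed closed form for it
#' is not used), including the attenuation introduced by the running-mean
#' subtraction, and cached per (f, d0, rate).
#'
#' @name morlet
NULL

#' Wavelet convolution half-window
#'
#' The frequency-dependent extent over which the Morlet convolution is
#' evaluated: `T_f = 2 d0 / (pi f)` seconds, the lag at which the wavelet's
#' Gaussian envelope has decayed by 98.2 percent.
#'
#' @param f Wavelet frequency (Hz).
#' @param d0 Decay parameter.
#' @return Half-window in seconds.
#' @export
wavelet_window <- function(f, d0 = 6) 2 * d0 / (pi * f)

.morlet_cache <- new.env(parent = emptyenv())

# Discrete conjugate Morlet kernel with trapezoid quadrature weights over
# [-T_f, T_f], plus the normalization C and the running-mean attenuation
# factor for frequency f at this sampling rate.
morlet_kernel <- function(f, rate, d0 = 6) {
  key <- sprintf("%.12g|%.12g|%.12g", f, rate, d0)
  hit <- .morlet_cache[[key]]
  if (!is.null(hit)) return(hit)

  dt <- 1 / rate
  Tf <- wavelet_window(f, d0)
  P <- max(1L, as.integer(round(Tf * rate)))
  s <- (-P:P) * dt
  g <- exp(-(2 * pi * f * s / d0)^2)
  k <- exp(-2i * pi * f * s) * g            # conj(M)/C on the grid
  w <- rep(dt, 2L * P + 1L)
  w[c(1L, 2L * P + 1L)] <- dt / 2           # trapezoid end weights
  kw <- k * w

  # running-mean window: extent T_f centered on t (odd sample count)
  h <- max(0L, as.integer(floor(Tf * rate / 2)))
  L <- 2L * h + 1L
  # Dirichlet factor of the discrete running-mean boxcar at frequency f
  D <- if (h == 0L) 1 else (1 + 2 * sum(cos(2 * pi * f * dt * seq_len(h)))) / L

  # exact discrete response of the unnormalized operator to a unit sinusoid
  # at f: the convolution contributes (sum G w)/2 per rotating component and
  # the center-subtracted running mean removes D * K0 / 2 of each
  K0 <- sum(kw)
  Aminus <- Re(sum(exp(2i * pi * f * s) * kw))   # = sum of the Gaussian weights
  resp <- (Aminus - D * Re(K0)) / 2
  if (resp <= 0) stop("degenerate wavelet normalization", call. = FALSE)
  out <- list(kw = kw, P = P, L = L, C = 1 / resp, Tf = Tf, K0 = K0)
  assign(key, out, envir = .morlet_cache)
  out
}

# full complex linear convolution via FFT
fft_conv <- function(x, k) {
  n <- length(x) + length(k) - 1L
  N <- stats::nextn(n, 2)
  y <- stats::fft(stats::fft(c(x, rep(0, N - length(x)))) *
                  stats::fft(c(k, rep(0, N - length(k)))), inverse = TRUE) / N
  y[seq_len(n)]
}

reflect_pad <- function(x, p) {
  n <- length(x)
  p <- min(p, n - 1L)
  c(x[(p + 1L):2L], x, x[(n - 1L):(n - p)])
}

# centered running mean over an odd window of L samples (O(n), cumsum-based)
running_mean <- function(x, L) {
  if (L <= 1L) return(x)
  h <- (L - 1L) %/% 2L
  xp <- reflect_pad(x, h)
  cs <- cumsum(c(0, xp))
  (cs[(L + 1L):(length(xp) + 1L)] - cs[seq_len(length(xp) - L + 1L)]) / L
}

#' Complex Morlet wavelet transform of a signal at one frequency
#'
#' Computes the finite-window convolution of the locally mean-subtracted
#' signal with the conjugate Morlet wavelet. The envelope is the modulus and
#' the phase the argument of the returned complex coefficients.
#'
#' @param x An [timeseries()] object.
#' @param f Wavelet frequency in Hz; must be at or below Nyquist.
#' @param d0 Dimensionless envelope-decay parameter (default 6).
#' @return A list with elements `coef` (complex vector, one per sample),
#'   `rate`, `t0`, `Tf` (window half-width, s).
#' @export
wavelet_transform <- function(x, f, d0 = 6) {
  stopifnot(inherits(x, "nsi_ts"))
  if (!is.numeric(f) || f <= 0) stop("`f` must be positive", call. = FALSE)
  if (f > x$rate / 2)
    stop(sprintf("wavelet frequency %g Hz above Nyquist (%g Hz)",
                 f, x$rate / 2), call. = FALSE)
  mk <- morlet_kernel(f, x$rate, d0)
  n <- length(x$samples)
  if (ts_duration(x) <= mk$Tf)
    stop(sprintf(
      "signal (%.3f s) shorter than the wavelet window T_f = %.3f s at %g Hz",
      ts_duration(x), mk$Tf, f), call. = FALSE)

  pad <- mk$P
  xp <- reflect_pad(x$samples, pad)
  rm_ <- running_mean(xp, mk$L)
  conv <- fft_conv(xp, mk$kw)
  # aligned slice: out[i] = sum_u xp[i - u] k[u], u in -P..P
  idx <- seq.int(mk$P + 1L, mk$P + length(xp))
  W <- (conv[idx] - rm_ * mk$K0) * mk$C
  W <- W[seq.int(pad + 1L, pad + n)]
  list(coef = W, rate = x$rate, t0 = x$t0, Tf = mk$Tf)
}

#' Wavelet envelope of a signal at one frequency
#'
#' Modulus of [wavelet_transform()]; a unit-amplitude sinusoid at `f` yields
#' an envelope of ~1 away from the edges. The first and last `T_f / 2`
#' seconds are edge-flagged.
#'
#' @inheritParams wavelet_transform
#' @return An [timeseries()] with nonnegative samples and the input's units.
#' @examples
#' x <- timeseries(sin(2 * pi * 10 * seq(0, 2, by = 1e-3)), rate = 1000)
#' env <- wavelet_envelope(x, f = 10)
#' mean(env$samples[ts_valid_mask(env)])
#' @export
wavelet_envelope <- function(x, f, d0 = 6) {
  wt <- wavelet_transform(x, f, d0)
  ts_like(x, samples = Mod(wt$coef), edge = max(x$edge, wt$Tf / 2))
}

#' Evenly spaced wavelet frequencies spanning a band
#'
#' Returns `n` frequencies uniformly spanning the closed band
#' `[f0 / w0, f0 * w0]` defined by a root frequency and a width factor.
#' `n = 1` returns the root frequency itself.
#'
#' @param f0 Root frequency (Hz, > 0).
#' @param w0 Width factor (>= 1).
#' @param n Number of wavelets (>= 1).
#' @return Nondecreasing numeric vector of length `n`.
#' @examples
#' band_frequencies(72.8, 1.83, 5)
#' @export
band_frequencies <- function(f0, w0, n) {
  if (!is.numeric(f0) || length(f0) != 1L || !is.finite(f0) || f0 <= 0)
    stop("`f0` must be a single positive frequency", call. = FALSE)
  if (!is.numeric(w0) || length(w0) != 1L || !is.finite(w0) || w0 < 1)
    stop("`w0` must be >= 1", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer", call. = FALSE)
  if (n == 1) return(f0)
  seq(f0 / w0, f0 * w0, length.out = n)
}

#' Band envelope: reduced wavelet envelopes over a frequency band
#'
#' Computes `n_wavelets` wavelet envelopes at frequencies evenly spanning
#' `band` and reduces them per sample by their mean or their maximum.
#' Mean reduction is the pLFP construction; max reduction is used for the
#' delta-band envelope entering the NSI.
#'
#' @param x An [timeseries()] object.
#' @param band Length-2 numeric, `c(f_lo, f_hi)` in Hz.
#' @param n_wavelets Number of evenly spaced wavelets (default 20).
#' @param reduce `"mean"` or `"max"`.
#' @param d0 Wavelet decay parameter.
#' @return An [timeseries()]; edge flag is the widest (lowest-frequency)
#'   wavelet's `T_f / 2`.
#' @export
band_envelope <- function(x, band, n_wavelets = 20, reduce = c("mean", "max"),
                          d0 = 6) {
  reduce <- match.arg(reduce)
  if (length(band) != 2L || band[1] <= 0 || band[2] < band[1])
    stop("`band` must be c(f_lo, f_hi) with 0 < f_lo <= f_hi", call. = FALSE)
  freqs <- if (n_wavelets == 1) sqrt(band[1] * band[2])
           else seq(band[1], band[2], length.out = n_wavelets)
  acc <- NULL
  for (f in freqs) {
    env <- wavelet_envelope(x, f, d0)$samples
    acc <- if (is.null(acc)) env
           else if (reduce == "mean") acc + env
           else pmax(acc, env)
  }
  if (reduce == "mean") acc <- acc / length(freqs)
  ts_like(x, samples = acc,
          edge = max(x$edge, wavelet_window(min(freqs), d0) / 2))
}

#' Gaussian temporal smoothing
#'
#' Convolution with a unit-area Gaussian kernel whose standard deviation is
#' `T` seconds (truncated at +/- 4 sd, reflection-padded). `T = 0` returns
#' the input unchanged.
#'
#' @param x An [timeseries()] object.
#' @param T Kernel standard deviation in seconds (>= 0).
#' @return An [timeseries()].
#' @export
gaussian_smooth <- function(x, T) {
  stopifnot(inherits(x, "nsi_ts"))
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T < 0)
    stop("`T` must be a single nonnegative duration (s)", call. = FALSE)
  if (T == 0) return(x)
  sd_samp <- T * x$rate
  h <- max(1L, as.integer(ceiling(4 * sd_samp)))
  k <- stats::dnorm(-h:h, sd = sd_samp)
  k <- k / sum(k)
  xp <- reflect_pad(x$samples, h)
  y <- Re(fft_conv(xp, as.complex(k)))
  y <- y[seq.int(h + 1L, h + length(xp))]
  ts_like(x, samples = y[seq.int(h + 1L, h + length(x$samples))])
}

#' Multi-unit activity (MUA) trace
#'
#' Population-spiking proxy: the absolute value of the 0.3-3 kHz band-passed
#' extracellular signal (zero-phase 4th-order Butterworth).
#'
#' @param x Wideband extracellular [timeseries()] sampled at >= 6 kHz.
#' @param band Pass band in Hz (default `c(300, 3000)`).
#' @return A nonnegative [timeseries()].
#' @export
mua_trace <- function(x, band = c(300, 3000)) {
  stopifnot(inherits(x, "nsi_ts"))
  if (x$rate < 2 * band[2])
    stop(sprintf("rate %g Hz too low for a %g Hz pass-band edge",
                 x$rate, band[2]), call. = FALSE)
  bf <- signal::butter(4, band / (x$rate / 2), type = "pass")
  y <- signal::filtfilt(bf, x$samples)
  ts_like(x, samples = abs(y))
}

#' Time-frequency spectrum (mean wavelet envelope per frequency)
#'
#' Time-averaged wavelet envelope at each requested frequency, excluding
#' edge-flagged samples. Frequencies inside the optional `blank` band (e.g.
#' power-line interference, 50 +/- 2 Hz) are reported as missing.
#'
#' @param x An [timeseries()] object.
#' @param freqs Frequencies to evaluate (Hz, all below Nyquist).
#' @param blank Optional length-2 band `c(lo, hi)` to blank out.
#' @param d0 Wavelet decay parameter.
#' @return A tibble with columns `freq` (Hz), `envelope` (signal units; NA
#'   inside the blanked band) and `blanked` (logical).
#' @export
tf_spectrum <- function(x, freqs, blank = NULL, d0 = 6) {
  if (length(freqs) < 1L) stop("`freqs` must be nonempty", call. = FALSE)
  blanked <- if (is.null(blank)) rep(FALSE, length(freqs))
             else freqs >= blank[1] & freqs <= blank[2]
  env <- vapply(seq_along(freqs), function(i) {
    if (blanked[i]) return(NA_real_)
    e <- wavelet_envelope(x, freqs[i], d0)
    mean(e$samples[ts_valid_mask(e)])
  }, numeric(1))
  tibble::tibble(freq = as.numeric(freqs), envelope = env, blanked = blanked)
}
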