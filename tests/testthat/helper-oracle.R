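# Independent oracle for the wavelet envelope: direct trapezoidal evaluation
# of the finite-window convolution integral at selected interior samples.
# No FFT, no shared code with the package's convolution path; the
# normalization is obtained by applying the same direct operator to a unit
# cosine and taking the reciprocal of its response ("normalized with respect
# to a sinusoid").

oracle_unnorm_coef <- function(samples, rate, f, d0, idx) {
  dt <- 1 / rate
  Tf <- 2 * d0 / (pi * f)
  P <- max(1L, as.integer(round(Tf * rate)))
  u <- -P:P
  s <- u * dt
  m0 <- exp(-2i * pi * f * s) * exp(-(2 * pi * f * s / d0)^2)
  w <- rep(dt, length(s))
  w[c(1L, length(s))] <- dt / 2
  h <- max(0L, as.integer(floor(Tf * rate / 2)))
  vapply(idx, function(i) {
    if (i - P < 1L || i + P > length(samples) ||
        i - h < 1L || i + h > length(samples))
      stop("oracle index too close to the edge")
    sm <- mean(samples[(i - h):(i + h)])
    sum((samples[i - u] - sm) * m0 * w)
  }, complex(1))
}

oracle_envelope <- function(x, f, d0 = 6, idx) {
  # normalization with respect to a sinusoid: the mean discrete response of
  # the operator (mean-subtraction + trapezoid quadrature) to a unit
  # sinusoid at f, written out independently of the package
  dt <- 1 / x$rate
  Tf <- 2 * d0 / (pi * f)
  P <- max(1L, as.integer(round(Tf * x$rate)))
  s <- (-P:P) * dt
  w <- rep(dt, length(s)); w[c(1L, length(s))] <- dt / 2
  gauss <- exp(-(2 * pi * f * s / d0)^2)
  h <- max(0L, as.integer(floor(Tf * x$rate / 2)))
  L <- 2L * h + 1L
  boxcar_gain <- if (h == 0L) 1 else
    (1 + 2 * sum(cos(2 * pi * f * dt * seq_len(h)))) / L
  kernel_sum <- Re(sum(exp(-2i * pi * f * s) * gauss * w))
  C <- 2 / (sum(gauss * w) - boxcar_gain * kernel_sum)
  C * Mod(oracle_unnorm_coef(x$samples, x$rate, f, d0, idx))
}

# brute-force episode validation oracle: double loop over grid points
oracle_validate <- function(samples, rate, t0, T_state, threshold,
                            edge = 0) {
  half <- T_state / 2
  t_end <- t0 + (length(samples) - 1) / rate
  centers <- seq(t0 + half, t_end, by = half)
  centers <- centers[centers + half <= t_end + 1e-9]
  edge_n <- ceiling(edge * rate)
  out <- logical(length(centers))
  for (k in seq_along(centers)) {
    lo <- round((centers[k] - half - t0) * rate) + 1
    hi <- round((centers[k] + half - t0) * rate) + 1
    if (lo <= edge_n || hi > length(samples) - edge_n) next
    w <- samples[lo:hi]
    out[k] <- (max(w) - min(w)) <= threshold
  }
  list(centers = centers, validated = out)
}
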