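#' Configuration of the synthetic paired LFP/Vm generator
#'
#' Emulates simultaneous extracellular LFP and membrane-potential (Vm)
#' recordings in awake cortex with a hidden ground-truth state sequence.
#' Rhythmic epochs carry a delta oscillation (default 3 Hz) that modulates
#' the LFP's high-gamma envelope and drives a stereotypical Vm oscillation;
#' nonrhythmic epochs sit at graded activity levels, with the Vm
#' depolarization coupled linearly (default 1.5 mV per uV of pLFP level) to
#' the LFP envelope level.
#'
#' @param duration Recording duration (s).
#' @param fs Sampling rate (Hz), default 10 kHz.
#' @param state_schedule Optional tibble with columns `label`
#'   ("rhythmic"/"nonrhythmic"), `level` (uV above the envelope floor) and
#'   `dwell` (s). `NULL` draws a random schedule at generation time.
#' @param delta_freq Delta oscillation frequency (Hz).
#' @param carrier_band High-gamma carrier band `c(lo, hi)` in Hz.
#' @param coupling_slope Vm depolarization per unit pLFP level in
#'   nonrhythmic states (mV/uV).
#' @param rhythmic_vm_amp Peak-to-trough amplitude of the stereotypical Vm
#'   delta oscillation in rhythmic states (mV).
#' @param vm_rest Resting membrane potential (mV).
#' @param noise_sd_lfp Broadband measurement noise on the LFP (uV).
#' @param noise_sd_vm Measurement/synaptic noise on the Vm (mV), low-passed
#'   at ~5 ms.
#' @param one_over_f_exponent Spectral exponent of the low-frequency LFP
#'   background (band-limited below the carrier band so the high-gamma
#'   ground truth stays exact).
#' @param background_sd SD of that low-frequency background (uV).
#' @param floor_level Residual high-gamma envelope in the absence of
#'   activity (uV); sets the true noise floor of the pLFP.
#' @param p_rhythmic Probability that a drawn state is rhythmic.
#' @param dwell_range Dwell-time range (s) for drawn states.
#' @param level_range_nonrhythmic,level_range_rhythmic Level ranges (uV) for
#'   drawn states.
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(duration = 300, fs = 10000, state_schedule = NULL,
                         delta_freq = 3, carrier_band = c(40, 130),
                         coupling_slope = 1.5, rhythmic_vm_amp = 7,
                         vm_rest = -70, noise_sd_lfp = 0.5,
                         noise_sd_vm = 0.3, one_over_f_exponent = 1,
                         background_sd = 20, floor_level = 2.5,
                         p_rhythmic = 0.25, dwell_range = c(2, 5),
                         level_range_nonrhythmic = c(0.5, 12),
                         level_range_rhythmic = c(2, 8),
                         seed = 1L) {
  stopifnot(duration > 0, fs > 0, delta_freq > 0,
            length(carrier_band) == 2L, carrier_band[1] > 0,
            carrier_band[2] > carrier_band[1], floor_level > 0,
            dwell_range[1] >= 2 / delta_freq)
  if (!is.null(state_schedule)) {
    state_schedule <- tibble::as_tibble(state_schedule)
    stopifnot(all(c("label", "level", "dwell") %in% names(state_schedule)))
    if (any(state_schedule$dwell < 2 / delta_freq))
      stop("dwell times must cover at least two delta cycles", call. = FALSE)
    if (any(state_schedule$level < 0)) stop("levels must be >= 0",
                                            call. = FALSE)
  }
  structure(as.list(environment()), class = "synth_config")
}

draw_schedule <- function(cfg) {
  total <- 0
  rows <- list()
  while (total < cfg$duration) {
    rhythmic <- stats::runif(1) < cfg$p_rhythmic
    dwell <- stats::runif(1, cfg$dwell_range[1], cfg$dwell_range[2])
    lr <- if (rhythmic) cfg$level_range_rhythmic else
      cfg$level_range_nonrhythmic
    rows[[length(rows) + 1L]] <- tibble::tibble(
      label = if (rhythmic) "rhythmic" else "nonrhythmic",
      level = stats::runif(1, lr[1], lr[2]),
      dwell = dwell)
    total <- total + dwell
  }
  dplyr::bind_rows(rows)
}

# band-limited 1/f^a noise via FFT spectral shaping, unit sd
shaped_noise <- function(n, fs, f_lo, f_hi, exponent = 0) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  freq <- c(seq(0, floor(n / 2)), seq(ceiling(n / 2) - 1, 1)) * fs / n
  gain <- numeric(n)
  inband <- freq >= f_lo & freq <= f_hi
  gain[inband] <- if (exponent == 0) 1 else freq[inband]^(-exponent / 2)
  y <- Re(stats::fft(spec * gain, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Generate a synthetic paired LFP/Vm recording with ground truth
#'
#' Constructs the LFP as band-limited high-gamma carrier noise whose
#' envelope follows the schedule's target pLFP level (modulated at
#' `delta_freq` by `1 + sin` during rhythmic states), plus a band-limited
#' 1/f background below the carrier band and white measurement noise. The
#' carrier is normalized so that the mean wavelet band envelope of a unit
#' carrier is 1, which makes the target pLFP level exact by construction.
#' The Vm is the resting potential plus `coupling_slope * level` during
#' nonrhythmic states, or the stereotypical delta oscillation (phase-locked
#' to the LFP envelope modulation) during rhythmic states, plus low-passed
#' noise.
#'
#' @param config A [synth_config()].
#' @return A list of class `nsi_synth` with elements `lfp` and `vm`
#'   ([timeseries()] objects, uV and mV), `truth` (a list with the realized
#'   `schedule`, 1-ms-resolution `state`, `target_plfp` and `target_vm`
#'   vectors plus their `rate`/`t0`), and `config`.
#' @examples
#' rec <- generate_recording(synth_config(duration = 12, fs = 2000, seed = 42))
#' rec$truth$schedule
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, generate_recording_impl(config))
}

generate_recording_impl <- function(cfg) {
  n <- as.integer(round(cfg$duration * cfg$fs))
  t <- (seq_len(n) - 1) / cfg$fs

  sched <- if (is.null(cfg$state_schedule)) draw_schedule(cfg) else
    cfg$state_schedule
  ends <- cumsum(sched$dwell)
  state_idx <- pmin(findInterval(t, c(0, ends[-length(ends)]),
                                 left.open = FALSE), nrow(sched))
  lab <- sched$label[state_idx]
  lev <- sched$level[state_idx]
  rhythmic <- lab == "rhythmic"

  osc <- 1 + sin(2 * pi * cfg$delta_freq * t)
  target_env <- cfg$floor_level + ifelse(rhythmic, lev * osc, lev)

  # carrier: band-limited white noise, normalized so that the mean wavelet
  # band envelope of the unit carrier equals 1
  carrier <- shaped_noise(n, cfg$fs, cfg$carrier_band[1], cfg$carrier_band[2])
  cal_n <- min(n, as.integer(30 * cfg$fs))
  cal_ts <- timeseries(carrier[seq_len(cal_n)], rate = cfg$fs)
  cal_env <- band_envelope(cal_ts, cfg$carrier_band, n_wavelets = 5,
                           reduce = "mean")
  carrier <- carrier / mean(cal_env$samples[ts_valid_mask(cal_env)])

  background <- cfg$background_sd *
    shaped_noise(n, cfg$fs, 0.1, 0.8 * cfg$carrier_band[1],
                 cfg$one_over_f_exponent)
  lfp <- carrier * target_env + background +
    cfg$noise_sd_lfp * stats::rnorm(n)

  target_vm <- cfg$vm_rest + ifelse(
    rhythmic, (cfg$rhythmic_vm_amp / 2) * osc, cfg$coupling_slope * lev)
  vm_noise <- gaussian_smooth(timeseries(stats::rnorm(n), rate = cfg$fs),
                              0.005)$samples
  vm_noise <- vm_noise / stats::sd(vm_noise) * cfg$noise_sd_vm
  vm <- target_vm + vm_noise

  # ground truth stored at the 1-ms analysis resolution
  dec <- max(1L, as.integer(round(cfg$fs / 1000)))
  idx <- seq(1L, n, by = dec)
  truth <- list(
    schedule = dplyr::mutate(sched, t_start = c(0, ends[-length(ends)]),
                             t_end = ends),
    state = lab[idx], target_plfp = target_env[idx],
    target_vm = target_vm[idx],
    rate = cfg$fs / dec, t0 = t[1])

  structure(list(
    lfp = timeseries(lfp, rate = cfg$fs, units = "uV"),
    vm = timeseries(vm, rate = cfg$fs, units = "mV"),
    truth = truth, config = cfg), class = "nsi_synth")
}

#' @export
print.nsi_synth <- function(x, ...) {
  cat(sprintf("<nsi_synth> %.1f s @ %g Hz, %d scheduled states (%.0f%% rhythmic time)\n",
              x$config$duration, x$config$fs, nrow(x$truth$schedule),
              100 * mean(x$truth$state == "rhythmic")))
  invisible(x)
}

#' Ground-truth state label at given times
#'
#' @param truth The `truth` element of a [generate_recording()] result.
#' @param times Times (s) to query.
#' @return Character vector of "rhythmic"/"nonrhythmic" labels.
#' @export
truth_label_at <- function(truth, times) {
  i <- pmin(pmax(1L, as.integer(round((times - truth$t0) * truth$rate)) + 1L),
            length(truth$state))
  truth$state[i]
}

#' Generate a band-coupled LFP/Vm pair for band-search validation
#'
#' Builds an LFP whose `band`-limited component carries a slowly varying
#' envelope, and a Vm equal to that envelope plus noise; the frequency band
#' maximizing the Vm/envelope correlation is then `band` by construction.
#' Used to validate [band_grid_search()].
#'
#' @param duration Duration (s).
#' @param fs Sampling rate (Hz).
#' @param band The coupled frequency band `c(lo, hi)` in Hz.
#' @param env_T Time constant (s) of the slow envelope fluctuations.
#' @param noise_sd_vm SD of the noise added to the Vm (envelope units).
#' @param distractor_sd SD of spectrally flat distractor noise in the LFP.
#' @param seed Integer seed.
#' @return A list with `lfp` and `vm` [timeseries()] objects.
#' @export
generate_band_coupled_pair <- function(duration = 60, fs = 400,
                                       band = c(60, 100), env_T = 0.3,
                                       noise_sd_vm = 0.1,
                                       distractor_sd = 0.3, seed = 1L) {
  withr::with_seed(seed, {
    n <- as.integer(round(duration * fs))
    z <- gaussian_smooth(timeseries(stats::rnorm(n), rate = fs), env_T)$samples
    env <- pmax(0.2, 1 + 0.5 * z / stats::sd(z))
    carrier <- shaped_noise(n, fs, band[1], band[2])
    lfp <- carrier * env + distractor_sd * stats::rnorm(n)
    vm <- env + noise_sd_vm * stats::rnorm(n)
    list(lfp = timeseries(lfp, rate = fs, units = "uV"),
         vm = timeseries(vm, rate = fs, units = "mV"))
  })
}
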