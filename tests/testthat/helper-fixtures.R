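# Shared fixtures, computed lazily once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# one moderately sized paired recording run through the whole pipeline
fixture_rec <- function() fixture("rec", function() {
  rec <- generate_recording(synth_config(duration = 90, fs = 2000,
                                         seed = 11L))
  plfp <- compute_plfp(rec$lfp)
  nsi <- compute_nsi(plfp)
  episodes <- validate_episodes(nsi, recording_id = "fixture")
  list(rec = rec, plfp = plfp, nsi = nsi, episodes = episodes)
})

# a synthetic ideal pLFP trace: p0 + delta * (1 + sin(2 pi f t))
ideal_rhythmic_plfp <- function(p0 = 3, delta = 4, f = 3, duration = 12,
                                rate = 1000) {
  t <- seq(0, duration, by = 1 / rate)
  timeseries(p0 + delta * (1 + sin(2 * pi * f * t)), rate = rate,
             units = "uV")
}

# wrap a bare NSI signal vector as an nsi_trace for validate_episodes()
as_nsi_trace <- function(samples, rate = 1000, p0 = 1,
                         params = nsi_params(fluct_threshold = p0)) {
  ts <- timeseries(samples, rate = rate, units = "uV")
  structure(list(delta_env = ts, x = ts, y = ts, nsi = ts, p0 = p0,
                 params = params, units = "uV"), class = "nsi_trace")
}
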