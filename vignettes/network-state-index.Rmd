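---
title: "Classifying cortical network states from the LFP: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cortical network states from the LFP: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsindex)
library(dplyr)
```

## The model

Cortical dynamics during wakefulness moves along a continuum of network
states. At one end sit delta-rhythmic states: stereotypical low-frequency
(2–4 Hz in S1, 4–8 Hz in V1) oscillations visible simultaneously in the
membrane potential (Vm) of single neurons and in population signals. The
rest of the continuum is nonrhythmic, ranging from hyperpolarized-quiet to
depolarized-active, with sensory performance typically best in the middle
("U-model"). The package classifies these states from the extracellular
LFP alone, using two physiological facts:

* the temporally smoothed **high-gamma envelope** of the LFP (the
  "pLFP") tracks the recruitment of local synaptic activity and hence the
  mean depolarization of nearby neurons during nonrhythmic epochs;
* during delta-rhythmic epochs the pLFP is **modulated at the delta
  frequency**, so its delta-band envelope measures the oscillation
  amplitude.

Writing `delta_env(t)` for the delta envelope of the pLFP, `Y(t)` for its
sliding mean and `p0` for its noise floor, a noiseless purely rhythmic
signal `pLFP = p0 + delta_env * (1 + sin(2 pi f t))` satisfies
`Y = p0 + delta_env`; any additional nonrhythmic drive pushes `Y` above
that. The rhythmicity criterion compares `X(t) = p0 + alpha * delta_env(t)`
against `Y(t)`: if `X >= Y` the oscillation accounts for the mean level and
the state is rhythmic (ties included), otherwise nonrhythmic. The signed
index is

```
NSI(t) = -2 * delta_env(t)           if X(t) >= Y(t)
          Y(t) - p0                  otherwise
```

so the magnitude of negative values is the peak-to-trough oscillation
amplitude and positive values are baseline-subtracted mean activity.

## The wavelet machinery

All envelopes come from a Morlet wavelet
`M(f, t) = C(f) exp(2 i pi f t) exp(-(2 pi f t / d0)^2)` with `d0 = 6`,
convolved (conjugated) against the signal after subtraction of its local
mean over the window `T_f = 2 d0 / (pi f)` centered on each sample — the
lag at which the wavelet envelope has decayed by `1 - exp(-4)` = 98.2%.
Two numerical choices matter:

* **Normalization is with respect to a sinusoid**, not the wavelet's own
  energy: `C(f)` is fixed so a unit-amplitude tone at `f` has envelope 1,
  keeping envelopes in the signal's physical units (µV, mV). `C(f)` is
  evaluated on the working sampling grid from the operator's exact discrete
  response to a unit sinusoid — including the small attenuation introduced
  by the running-mean subtraction (a Dirichlet factor of the discrete
  boxcar; ignoring it biases envelopes by ~4% because `T_f` is not an
  integer number of periods). The identity then holds to ~1e-5 across
  [2, 200] Hz, and the test suite asserts it at 2%.
* **Edge handling**: convolutions use reflection padding, and the first and
  last `T_f / 2` of every envelope trace are flagged as edge; averages,
  correlations and episode validation exclude the flagged margins.

The transform is computed by FFT convolution with trapezoid quadrature
weights over `[-T_f, T_f]`; the tests verify agreement with direct
trapezoidal evaluation of the convolution integral to 1e-6 relative. The
same machinery provides the multi-unit activity proxy (rectified 0.3–3 kHz
band; zero-phase 4th-order Butterworth, since only the band is prescribed
by convention) and time–frequency spectra with optional power-line
blanking.

## Parameters and their defaults

| Parameter | Default | Meaning |
|---|---|---|
| `f0`, `w0` | 72.8 Hz, 1.83 | pLFP band `[f0/w0, f0*w0]` ≈ [39.8, 133.2] Hz |
| `n_wavelets` | 5 | wavelets evenly spanning the band |
| `T_smoothing` | 42.2 ms | Gaussian smoothing of the band envelope |
| `p0_percentile` | 1% | percentile defining the noise floor p0 |
| `delta_band` | [2, 4] Hz | delta band (S1); [4, 8] Hz in the V1 preset |
| `n_delta_wavelets` | 20 | wavelets sampling the delta band (max-reduced) |
| `T_mean` | 500 ms | sliding-mean window of Y(t) |
| `alpha` | 2.87 | rhythmicity factor (3.07 in the V1 preset) |
| `T_state` | 400 ms | episode window; grid step T_state/2 |
| `fluct_threshold` | p0 | episode-validation fluctuation bound |

The band, smoothing and alpha defaults are the values calibrated on
simultaneous Vm/LFP recordings in awake mouse S1 and ship as the `s1`
preset; they are data-set properties, not universal constants, which is
why the calibration module exists. The `v1` preset (delta [4, 8] Hz,
30-ms smoothing, alpha = 3.07) matches the faster delta rhythm of mouse
V1. "Gaussian smoothing of time constant T" is interpreted as the
kernel's standard deviation (truncated at ±4 sd); percentiles use linear
interpolation between order statistics (type-7 quantiles); 1-ms
downsampling is by bin-averaging with bins anchored at t0 and a partial
final bin dropped, applied after smoothing.

## Episode validation and degenerate inputs

Episodes are 400-ms windows on a 200-ms grid starting at `t0 + T_state/2`;
a window is validated iff max − min of NSI within it is at most the
fluctuation threshold. Windows extending past the recording or into the
edge-flagged margins are unclassified. A validated episode's NSI is the
center sample (the window mean is available as an option; the choice is
immaterial for stable windows, which validation guarantees). Ties
`X = Y` go to the rhythmic branch, so a trace pinned at the baseline is
the rhythmic boundary case with NSI = 0. Constant traces validate
everywhere; traces shorter than one window return an empty table with a
warning.

## Calibration

The band search follows a two-stage presentation rather than a joint 3-D
search: Pearson correlation (zero lag) between the reference and the
un-smoothed band envelope on an (f, w) grid, averaged over recordings;
then a smoothing sweep at the optimum, each recording's curve normalized
by its maximum and referenced to its T = 0 value.

The rhythmicity factor is calibrated by sweeping alpha, classifying
episodes at each value, and averaging the reference signal's delta
envelope over the rhythmic set (a recording contributes only where it has
more than five rhythmic episodes). The curve decays as nonrhythmic
episodes dilute the rhythmic set, and the decay constant of
`A * exp(-alpha / lambda) + B` is the calibrated alpha. Two choices make
this fit well-posed, both genuinely open in the construction:

* the fit starts at the curve's maximum: at very small alpha the rhythmic
  set degenerates to near-silent episodes (an oscillation trivially
  accounts for a near-baseline mean level), which sit at the contamination
  floor rather than on the decay;
* the offset `B` is not free but fixed at its interpretable large-alpha
  limit — the mean reference delta envelope over *all* validated episodes —
  because a free three-parameter exponential is ill-conditioned on a
  slowly decaying arc.

## Cross-validation against the membrane potential

The Vm-defined NSI uses the same parameters with the noise floor replaced
by the 1st percentile of the Vm distribution and a 2-mV validation
threshold. The scaling factor F between the two indices is a least-squares
slope through the origin, fitted only on sign-concordant episodes (an
intercept variant exists but is off by default — F is a scaling factor).
An episode is correct iff `|F * NSI_Vm - NSI_pLFP| < F * vm_tol + p_tol`
(defaults 2 mV and 2.85 µV): the two tolerance intervals must overlap, a
reading under which widening either tolerance can only increase accuracy.
Accuracy is computed over episodes validated in **both** indices; episodes
validated in only one are counted separately, not as errors. Misclassified
episodes are split into the four sign combinations of the two indices.
Action potentials are not removed from the Vm by default; spiking inflates
the Vm delta envelope slightly but the validation threshold suppresses
spike-dominated windows.

## The synthetic generator

`generate_recording()` emulates the study conditions: a hidden schedule of
rhythmic and nonrhythmic states (dwell 2–5 s, 25% rhythmic draw
probability, levels 0.5–12 µV nonrhythmic and 2–8 µV rhythmic above a
2.5-µV envelope floor), a high-gamma carrier (band-limited white noise,
normalized so that a unit carrier has unit band envelope, multiplied by
the target envelope — making the pLFP demodulation target exact by
construction), delta modulation `1 + sin(2 pi f t)` at 3 Hz during
rhythmic states, a band-limited 1/f background kept *below* the carrier
band so the high-gamma ground truth stays exact, and white measurement
noise (0.5 µV). The Vm is `-70 mV + 1.5 mV/µV × level` during nonrhythmic
states — the depolarization coupling reported for awake S1 — and a
stereotypical 7-mV peak-to-trough delta oscillation, phase-locked to the
LFP modulation, during rhythmic states, plus low-passed noise (0.3 mV).
Levels and couplings were fixed from the phenomenology the index is built
to detect and are not tuned per test.

What the generator does *not* emulate: spikes in the Vm (optional
insertion is deliberately out of scope), electrode drift, movement
artifacts, state-dependent changes in noise, or genuinely graded
rhythmicity inside a single state (labels are crisp by design so that
ground-truth recovery is well-defined). Passing tests therefore
demonstrate correctness of the machinery under the stated phenomenology,
not performance on any particular real dataset; the shipped defaults'
published provenance is the users' anchor there.

## Problem sizes in the test suite

The suite and the acceptance script use 1–5-minute recordings at 2 kHz
(the method operates at 1 kHz after binning; 2 kHz comfortably covers the
133-Hz band edge), 2–4 recordings per cohort for calibration and slope
recovery, and a 50-recording synthetic feature cohort for the regression
analyses. These sizes give a few hundred to ~1500 validated episodes per
check — enough that the stochastic tolerances (5–10%) sit several standard
errors from the pass boundaries.

## Known limitations

* Rhythmicity is judged from the pLFP, which can miss delta oscillations
  that are strong in the Vm but weak in the population signal; on
  asymmetric synthetic data the dominant error is accordingly
  "nonrhythmic by pLFP, rhythmic by Vm", and users should expect the same
  bias on real recordings.
* p0 is a whole-recording statistic; slow drifts in electrode coupling
  violate its stationarity assumption.
* NWB containers are not read in this build; convert to CSV or flat
  binary + sidecar upstream (`read_timeseries()` documents both).
* The episode grid is fixed (400 ms / 200 ms); much faster state switching
  than the delta time scale is by construction unclassifiable.
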