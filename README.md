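# nsindex

Classification of cortical network states from extracellular local field
potential (LFP) recordings via the **Network State Index (NSI)**.

## The problem

In the awake cortex, network activity wanders along a continuum of states:
epochs of low-frequency rhythmic activity in the delta band (2–4 Hz in
somatosensory cortex, 4–8 Hz in visual cortex) alternate with nonrhythmic
epochs at graded levels of depolarization and population firing. These
states strongly modulate sensory processing, but their reference
characterization requires intracellular membrane-potential (Vm) recordings,
which are hard to obtain. `nsindex` implements an LFP-only state
classifier for electrophysiologists who record extracellular signals —
glass pipettes, silicon probes, Neuropixels — and want the state
information that Vm recordings would give.

## The method

1. **pLFP.** The LFP is transformed into its "processed LFP": the mean of
   N = 5 Morlet wavelet envelopes evenly spanning the high-gamma band
   [f0/w0, f0·w0] (defaults f0 = 72.8 Hz, w0 = 1.83, i.e. ≈[39.8, 133.2] Hz),
   Gaussian-smoothed (T = 42.2 ms) and bin-averaged to 1-ms resolution.
   The wavelet is normalized against a sinusoid, so a unit-amplitude tone
   at the wavelet frequency has envelope 1. The noise floor p0 is the 1st
   percentile of the pLFP distribution.
2. **NSI.** With the delta envelope δ_env(t) (maximum of 20 wavelet
   envelopes over the delta band), the sliding mean Y(t) (Gaussian,
   T_mean = 500 ms), and the rhythmicity estimate X(t) = p0 + α·δ_env(t)
   (α = 2.87):

   NSI(t) = −2·δ_env(t)·H(X−Y) + (Y(t)−p0)·H(Y−X)

   where H is the Heaviside step. Negative NSI measures delta-oscillation
   amplitude (rhythmic states); positive NSI the baseline-subtracted mean
   activity (nonrhythmic states).
3. **Validated episodes.** The time axis is scanned in steps of
   T_state/2 = 200 ms; a 400-ms window is a *validated* episode iff the
   NSI fluctuates less than p0 within it, otherwise it is unclassified.
4. **Calibration & cross-validation.** With simultaneous Vm (or a
   population rate), the package calibrates the band (grid search on the
   Vm/envelope correlation), the smoothing, and α (decay constant of the
   Vm delta envelope across rhythmic states as a function of α), computes a
   Vm-defined NSI, fits the scaling factor F between the two indices, and
   scores tolerance-box accuracy with a four-way misclassification
   taxonomy.

A synthetic paired-recording generator with hidden ground-truth state
schedules makes the entire chain testable without data.

## Worked example

```r
library(nsindex)
library(dplyr)

rec <- generate_recording(synth_config(duration = 120, fs = 2000, seed = 7))
plfp <- compute_plfp(rec$lfp)            # high-gamma envelope + noise floor
nsi  <- compute_nsi(plfp)                # NSI trace (alpha = 2.87)
ep   <- validate_episodes(nsi)           # episode table on the 200-ms grid
state_fractions(ep)
#> # A tibble: 3 × 3
#>   label            n percent
#>   <chr>        <int>   <dbl>
#> 1 rhythmic       147    24.6
#> 2 nonrhythmic    384    64.2
#> 3 unclassified    67    11.2

# cross-validate the LFP index against the membrane potential
ep_vm  <- validate_episodes(compute_vm_nsi(rec$vm))
paired <- pair_episodes(ep, ep_vm)
fit    <- fit_scale_factor(paired)
evaluate_accuracy(paired, fit)
#> <nsi_accuracy> 91.8% correct over 490 jointly validated episodes
#>   F = 0.6318 uV/mV, tolerances: 2.85 uV / 2 mV; 71 episodes validated in one index only
```

The fractions are the time shares of delta-rhythmic, nonrhythmic and
unstable (unclassifiable) network states; the accuracy is the percentage
of episodes in which the LFP-based index predicts the Vm-based index
within the tolerance box after scaling by F (in µV of pLFP-NSI per mV of
Vm-NSI).

Each result object has `tidy()` / `glance()` accessors and an
`autoplot()` method; a thin command-line front-end (`inst/exec/nsi`, or
`nsi_main()`) exposes `synth`, `compute`, `validate`, `analyze`,
`calibrate-band` and `calibrate-alpha` subcommands over CSV/TSV files.

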