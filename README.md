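# localsleep

Analysis pipeline for experiments in which the thalamic reticular
nucleus (TRN) is tonically activated with optogenetics while cortical
LFP/EEG, EMG and spiking are recorded. Low arousal states are marked by
1–4 Hz (delta) slow waves and by *OFF periods* — stretches of ≥ 50 ms
with zero population firing, phase-locked to slow-wave troughs. The
package quantifies how laser stimulation changes these signatures and
how they relate to behavioural arousal, and ships a synthetic-session
generator with ground-truth labels so every estimator can be verified by
parameter recovery.

It is written for systems-neuroscience users analysing trial-structured
optogenetics sessions (30 s stimulation blocks separated by rest), or
anyone needing the individual components: multitaper band-power
statistics, slow-wave and OFF-period detectors, phase-locking measures,
spike-history GLMs, rule-based sleep scoring, optical-flow motion
scoring, or the fiber irradiance model.

## What it computes

* **Spectral effects** — DPSS multitaper spectra (19 tapers / 30 s
  windows; spectrograms 5 tapers / 5 s / 1 s step), per-trial paired
  band-power changes in dB with Hodges–Lehmann medians and 95% CIs by
  Wilcoxon signed-rank inversion, Bonferroni-corrected per-channel
  delta-effect maps.
* **Slow-wave events** — 0.1–5 Hz zero-phase FIR filtering, troughs
  < −100 µV, artifact rejection (±200 ms raw SD > 2000 µV), top 3% of
  peak-to-peak amplitudes per session; event-rate and amplitude
  statistics.
* **OFF periods** — pooled-spike silence ≥ 50 ms under a 20 ms Gaussian
  rate kernel; chance level from a gamma-renewal null (MLE fit to ISIs,
  1000 surrogate trains); chi-square test of OFF-phase uniformity.
* **Phase locking** — instantaneous delta phase (FIR + Hilbert), PLV
  with 500 trial-shuffle permutations, Kullback–Leibler modulation
  index MI = Σ pᵢ log₂ pᵢ + log₂ n over 10 (spike) or 100 (gamma
  envelope) phase bins, circular-kurtosis group comparisons.
* **Units & GLMs** — Narrow/Wide waveform classification at 200 µs,
  paired rate changes, bootstrap onset-latency detection in 10 ms bins
  (α = 0.005), and discrete-time point-process GLMs with 50 × 2 ms
  binary spike-history covariates, comparing the (2, 4] ms coefficient
  across conditions by CI overlap.
* **Behaviour** — EMG band power (10–200 Hz), semi-automated EEG/EMG
  sleep scoring (wake / NREM / REM per second), state-occupancy changes,
  Horn–Schunck optical-flow motion traces, EEG–EMG coupling with
  shuffle tests, and shuffled-onset controls within NREM.
* **Light model** — irradiance below the fiber,
  I(z) = I₀·ρ²/((Sz+1)(z+ρ)²) with ρ = r·√((n/NA)²−1), plus the depth at
  which irradiance falls to an activation threshold.

## Worked example

```r
library(localsleep)

## ten 30 s laser trials; inject a +2.5 dB delta effect
tr <- trial_set(onsets = 30 + (0:9) * 120, offsets = 30 + (0:9) * 120 + 30)
g  <- generate_lfp(duration_s = 1240, trials = tr, delta_effect_db = 2.5, seed = 1)

band_power_change(g$trace, g$fs, tr, band = c(1, 4))
#> band 1-4 Hz: change = 2.41 dB, CI = [1.96 2.82], n = 10 trials, p = 0.00195

## OFF periods at the injected slow-wave troughs, against the renewal null
offs <- place_off_periods(g$ground_truth$trough_times, seed = 1)
sp   <- generate_spike_train(1240, base_rate_hz = 12, off_periods = offs, seed = 2)
nul  <- off_fraction_null(sp$spike_times, 0, 1240, n_sims = 500, seed = 3)
#> OFF time: 15.05% observed vs 13.99% [13.37 14.73] under the renewal null

## depth of supra-threshold illumination for a 0.21 NA, 200 um fiber
tis <- tissue_params(preset = "paper")
stimulated_depth(fiber_spec(power_mw = 1), tis, threshold_mw_mm2 = 1)  # 0.40 mm
stimulated_depth(fiber_spec(power_mw = 3), tis, threshold_mw_mm2 = 1)  # 0.75 mm
```

The recovered delta change (2.41 dB, CI excluding 0) matches the 2.5 dB
injection; the OFF-period fraction exceeds the 97.5th percentile of the
gamma-renewal null, as it should when silences are imposed on top of
renewal firing; and tripling the laser power nearly doubles the
stimulated depth because scattering attenuation is exponential-like
while cone spread is geometric.

Full sessions run end to end with `run_pipeline(analysis_config(seed = 1),
session, "out/")`, which writes per-stage CSVs, a consolidated
`stats.json` and diagnostic figures; `simulate_session(preset =
"awake-stim")` builds a complete synthetic session. A thin command-line
wrapper is installed at `inst/cli/localsleep`
(`localsleep simulate|all|light ...`).

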