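---
title: "Methods: slow waves, OFF periods and arousal state with localsleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slow waves, OFF periods and arousal state with localsleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`localsleep` implements the analysis chain used to characterise how tonic
optogenetic activation of the thalamic reticular nucleus (TRN) induces
local cortical slow waves, neuronal OFF periods and reduced behavioural
arousal. This vignette documents the models and procedures, the
parameters that matter, the synthetic-data generator used to verify each
stage by parameter recovery, and the numerical choices made where a
published description leaves the implementation open.

## Spectral statistics

Spectra are DPSS multitaper estimates. Stationary spectra use 19 tapers
over 30 s windows and spectrograms 5 tapers in 5 s windows stepped every
1 s; in both cases the time-bandwidth product follows the K = 2NW − 1
convention (NW = 10 and NW = 3 respectively). Tapers are computed from
the standard symmetric tridiagonal eigenproblem; for windows longer than
1024 samples they are computed at 1024 points, spline-interpolated to
full length and re-normalised to unit energy — the same shortcut common
multitaper implementations offer for long windows. Spectra are one-sided
densities in µV²/Hz, so integrating `power * df` recovers the trace
variance.

Band power is the sum of density × frequency-step over grid frequencies
inside the band, both edges inclusive. All power changes are expressed
as `10 * log10(ratio)` dB. The beta/gamma band defaults to 15–50 Hz with
a 12–50 Hz variant available in the configuration (`band_beta_gamma_alt`),
since both conventions appear in the literature this pipeline follows.

Laser effects are paired per trial: band power in the 30 s stimulation
window against the 30 s immediately preceding onset. The effect size is
the Hodges–Lehmann estimate with a 95% CI obtained by inverting the
Wilcoxon signed-rank test (`stats::wilcox.test(conf.int = TRUE)`, exact
for small tie-free samples, normal approximation otherwise). Normalized
spectrograms take the median across trials *first*, then divide each
frequency by its mean over the pre-stimulus window — in that order, which
is the order the underlying procedure states.

The per-channel delta-effect map carries two labellings: (a)
Bonferroni-corrected signed-rank significance across channels, and (b) a
normalized-delta flag set when delta power as a fraction of 0–50 Hz
power rises by at least 2 percentage points.

## Slow-wave events

The LFP is bandpassed 0.1–5 Hz with a zero-phase FIR filter
(windowed-sinc, order `3 * fs / f_lo` capped at a third of the record,
applied by FFT convolution with the group delay removed). Local minima
below −100 µV are candidate troughs; peak-to-peak amplitude is the first
subsequent local maximum minus the trough. Candidates whose surrounding
±200 ms of *raw* LFP exceeds 2000 µV standard deviation are rejected
before ranking. The top 3% of peak-to-peak amplitudes within a session
are kept.

Two open points were resolved as follows. The 3% percentile is taken
over the thresholded candidates (not all minima). Selection is by rank —
exactly `ceiling(0.03 * n)` events, equal amplitudes ordered by time —
rather than "keep all ties at the boundary": on a perfectly periodic
input every candidate ties, and a tie-keeping rule would return all of
them, which contradicts both the closed-form event count and the spirit
of a percentile selection.

## OFF periods

Single- and multi-unit spikes are pooled and an instantaneous rate is
defined through a Gaussian kernel (SD 20 ms, truncated at ±4 SD); OFF
periods are maximal stretches of at least 50 ms with zero rate. Because
"zero rate" under a truncated kernel means *no spike within the
truncated support*, the detector uses exact interval arithmetic on spike
gaps: a gap `g` contributes an OFF period of `g − 2·(4·SD)` when that
remainder reaches 50 ms. This is equivalent to thresholding the gridded
smoothed rate at ε = 10⁻⁹ Hz but exact and fast; the gridded rate is
still exposed (`smoothed_rate`) for inspection. Gaps at the record edges
count as OFF periods by documented contract (`include_edges = FALSE` to
drop them).

The chance level is a renewal null: a gamma distribution is fitted to
the observed inter-spike intervals (maximum likelihood via
`MASS::fitdistr`, method-of-moments fallback) and surrogate trains with
the same spike count are drawn 1000 times; the observed percent of time
in OFF periods is compared with the 2.5th–97.5th percentile band of the
simulated fractions. The phase preference of OFF periods is tested by
assigning each period's midpoint a delta phase, binning into 10 bins and
applying Pearson's chi-square against uniformity (dof = 9).

## Phase locking

Instantaneous delta phase is the angle of the analytic signal (FFT
Hilbert transform) of the 1–4 Hz zero-phase-filtered trace; samples
within one filter half-length of the record edges are flagged invalid.
Troughs sit at ±π.

The phase-locking value between two channels is the magnitude of the
circular mean of the per-sample phase difference over trial windows; its
null distribution comes from 500 shuffles of the trial pairing, and the
offset angle gets a 500-resample percentile bootstrap CI.

The modulation index (MI) is the Kullback–Leibler distance of a
phase-binned distribution from uniform, in bits: `Σ p_i log2 p_i +
log2 n_bins`, 0 for uniform and `log2 n_bins` when one bin holds
everything. Spike MI uses 10 bins of spike counts, with the preferred
phase the centre of the fullest bin. Gamma MI uses 100 bins of the mean
70–100 Hz envelope per bin (normalised to sum 1); a least-squares
sinusoid fitted to the binned profile supplies the preferred phase only
— folding the fit into the MI itself would make the index depend on two
different estimators at once, so the two roles are kept separate. The
gamma filter uses a full second of taps: with typical LFPs the
low-frequency component is two orders of magnitude larger than gamma,
and a short filter's stopband leaks enough of it to corrupt the
envelope.

Group differences in the narrowness of peak-phase distributions use the
circular kurtosis (`mean(cos(2(α − μ)))`) compared between unit groups,
with significance from 1000 shuffles of the group assignment.

## Units and spike-history GLMs

Units are classified Narrow (< 200 µs waveform peak-to-trough) or Wide
(≥ 200 µs; the boundary value is Wide by documented tie-break). Rate and
MI changes are paired per trial and summarised by signed-rank inversion
like the spectral effects.

Onset latency uses 10 ms bins: the 2 s pre-stimulus period provides 200
baseline bin means, whose 0.25th percentile (α = 0.005, correcting for
the 10 post-onset bins tested) is bootstrapped 1000 times; the threshold
is the lower 95% confidence bound of that percentile, which keeps the
family-wise false-alarm rate near 2α on null data (verified by
simulation). The first post-onset bin below threshold is reported; the
LFP variant averages the mean voltage per bin instead of spike counts.

Spike-history dependence is modelled as a discrete-time point process:
2 ms bins, Poisson likelihood with log link, and binary spike-occupancy
covariates at lags 1..50 (lag bins never cross analysis-window
boundaries). The paper-facing quantity is the coefficient of the second
lag bin, covering (2, 4] ms; a condition change is called significant
when the two 95% Wald CIs do not overlap (a Wald z-test alternative is
selectable). Poisson/log is the standard discretisation when the
original fit family is unstated; fits that fail to converge or produce a
singular information matrix are flagged and excluded downstream.

## Sleep scoring and behaviour

Wake is detected from the 60–200 Hz EMG envelope (Gaussian-smoothed,
50 ms SD): runs of at least 5 s above a threshold. Remaining time is
split by the smoothed (1 s SD — unstated in the source procedure, chosen
as one EEG scoring epoch) ratio of <4 Hz to 4–16 Hz EEG power: above
threshold NREM, below REM, with REM bouts not preceded by ≥ 10 s of NREM
relabelled wake (manual scorers implicitly apply this rule; without it,
quiet wake is misread as REM). Thresholds are semi-automated: caller
supplied, or suggested by 2-means clustering of the per-second EMG
envelope with a quality flag when the clusters do not separate. EMG
*power* effects use the broader 10–200 Hz band in 1 s windows — the two
bands differ deliberately, matching their distinct uses.

Motion scoring computes Horn–Schunck optical flow per frame pair
(regularisation α² = 1, 100 iterations, intensities scaled to [0, 1]),
takes the magnitude of the maximal-flow point per frame, normalises the
trace by its mean (making it robust to lighting and camera placement)
and smooths with a moving average (default 200 frames).

The EEG–EMG coupling statistic is the Pearson correlation of per-trial
delta-power changes against EMG-power changes, with a paired bootstrap
CI and significance against the 97.5th percentile of the correlation
under shuffled trial pairings. The shuffled-onset control re-computes
any onset-locked statistic at 400 sets of pseudorandom onsets placed
inside spontaneous NREM (with a 30 s NREM margin) and reports the null
95% interval.

## Fiber irradiance

Irradiance below the fiber combines geometric cone spread with
Kubelka–Munk scattering:

I(z) = I₀ · ρ² / ((S·z + 1)(z + ρ)²),  ρ = r·√((n/NA)² − 1)

with I₀ = P/(πr²) the surface irradiance, n the tissue refractive index
and S the scattering coefficient. The generic preset uses published
mouse gray-matter values (n = 1.36, S = 11.2 mm⁻¹). Because the closed
form with generic constants need not reproduce any particular published
calculator, a calibration mode (`calibrate_tissue`) solves the 2×2
linear system for S and a fiber transmission fraction such that two
anchor (power, depth) pairs at a given activation threshold are met
exactly; the `"paper"` preset is calibrated against depths of 0.4 mm at
1 mW and 0.75 mm at 3 mW for a 1 mW/mm² threshold through a 0.21 NA,
200 µm fiber, yielding S = 8.68 mm⁻¹ and transmission 0.371. The
transmission fraction has a physical reading — bench-measured laser
power is always scaled down for coupling and fiber losses before
reporting power in the brain. Stimulated depth is the unique root of
I(z) = threshold, found by bisection to 10⁻⁴ mm.

## The synthetic-session generator

The generator emulates exactly the statistical structure the analyses
assume, with ground-truth labels:

* **LFP**: 1/f background (power exponent 1, the standard LFP
  assumption; RMS 50 µV) plus, during laser-ON, an asymmetric slow wave
  — fundamental (default 1.7 Hz, placing the phase-locked second
  harmonic at 3.4 Hz, inside the delta band) minus an `asymmetry × `
  second harmonic, making troughs deeper than peaks. The oscillation
  amplitude is calibrated against the *multitaper* delta band power of
  the generated background so that the realised dB change matches the
  requested injection. 70–100 Hz amplitude is modulated by the
  oscillator phase during ON.
* **Spikes**: discrete-time thinning at 1 ms of a conditional intensity
  = base rate × von Mises phase modulation (normalised to mean 1) ×
  multiplicative per-2 ms-lag history gains × an OFF mask that forces
  zero intensity inside ground-truth OFF periods. OFF periods sit at
  slow-wave troughs with jitter; durations are log-normal with median
  122 ms (a literature-informed default, not a claim).
* **EEG/EMG**: state sequences with EMG amplitude high in wake, strong
  delta plus 12 Hz spindle transients in NREM, and theta in wake/REM.

What the generator does *not* emulate: non-stationary background
spectra, volume conduction between channels, electrode drift, real
spindle morphology, movement artifacts beyond simple >2000 µV
excursions, and spike-sorting errors. Passing parameter-recovery tests
therefore demonstrates the correctness of the estimators under the
stated model, not robustness to every pathology of real recordings.

## Reproducibility and problem sizes

One global seed lives in the configuration; every stochastic stage
derives its own seed by stable hashing of the stage name, so adding or
reordering stages never perturbs another stage's stream, and the full
pipeline is bit-reproducible. The test suite runs everything at desk
scale, chosen to keep the whole suite around three minutes on one core:
20-trial sessions for spectral recovery (realised injection within
±0.5 dB), 600 s spike trains for the OFF-period null (400 simulations
per test), 100-unit cohorts of 120 s / 10 Hz trains for the GLM
false-positive rate, and 200 replicates for CI-coverage checks. The
vignette's companion numbers (e.g. the 0.4 mm / 0.75 mm depths, the
0.37 and 0.26 posterior differences) are recomputed by
`scripts/acceptance.R`.

## Known limitations

* The DPSS interpolation shortcut trades a little taper orthogonality
  for speed on long windows; band-power integrals are accurate to well
  under the 5% the tests require, but exact eigenvalue concentrations
  are not reported.
* The history GLM uses binary occupancy covariates, so multiple spikes
  inside one 2 ms bin are collapsed; at cortical rates this is rare.
* Sleep scoring is rule-based and inherits the thresholds' quality; the
  automatic suggestion is a convenience, not a replacement for the
  semi-automated (manually thresholded) procedure it mirrors.
* The irradiance model is a closed-form approximation; the calibrated
  preset guarantees agreement at its two anchor points only.
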