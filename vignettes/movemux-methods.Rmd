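---
title: "Movement, glucose and phase multiplexing in photometry signals: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement, glucose and phase multiplexing in photometry signals: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(movemux)
```

## The analysis in one paragraph

A head-fixed mouse on a wheel is filmed while the bulk calcium activity of a
hypothalamic neuron population (hypocretin/orexin neurons, HONs) is recorded
by fiber photometry. `movemux` implements the analysis chain that relates
the two: a one-dimensional *movement metric* — the summed absolute per-pixel
difference between consecutive video frames, convolved with an exponential
kernel matched to the GCaMP6s indicator half-life (1.796 s) and z-scored —
is compared with the preprocessed photometry signal by whole-session
correlation, cross-correlation lag, mixed-effects model comparison, and,
after empirical mode decomposition (EMD), by per-frequency-band regression
and circular phase statistics. The central claims these tools can test are
that (i) the population signal tracks the instantaneous magnitude of body
movement, (ii) movement and the first derivative of blood glucose occupy
*distinct frequency bands* of the same signal (movement at 0.1–0.01 Hz,
glucose below 10^-3^ Hz), and (iii) movement is phase-aligned to the
signal's oscillations (active epochs at the crest, quiescent epochs at the
trough).

## Movement metric

`frame_difference()` sums |Δpixel| between consecutive 8-bit frames
(differencing is done in doubles so unsigned 8-bit arithmetic can never wrap
around); the first frame yields no sample. `gcamp_kernel()` builds a 60 s
decaying exponential with half-life 1.796 s and peak 1 — the peak
normalization is irrelevant because the metric is z-scored afterwards, and a
test asserts this scale invariance. `movement_metric()` convolves causally
("full" convolution truncated to the input length: the kernel models
indicator decay *after* movement), removes the first 60 s of convolution,
and z-scores the remainder by its own mean and SD. Statistics always use
this raw metric; `smooth_for_display()` exists only for plotting and flags
its output accordingly.

## Photometry preprocessing

`preprocess_photometry()` removes the first minute (bleaching artifacts),
subtracts a least-squares triple exponential
`c0 + Σ a_i exp(-t/τ_i)` (amplitudes constrained non-negative; initial time
constants duration/2, duration/10, duration/50 span the bleaching scales;
non-convergence falls back to double then single exponential, recorded in
the result), and z-scores. The isosbestic channel receives the same
processing and is used **only** for quality control
(`isosbestic_qc()` flags |r| between isosbestic and movement above 0.3 by
default): no regression-based artifact subtraction is applied, since the
control channel's role here is detection, not correction. The 0.3 default is
an explicit stand-in — no quantitative artifact criterion is established for
these recordings — and is surfaced in the configuration.

## Empirical mode decomposition

`sift()` implements classic sifting: cubic-spline envelopes through local
extrema (two extrema mirrored about each end), envelope-mean subtraction
iterated until a Cauchy criterion (energy of the removed mean below 0.2 of
the iterate's energy), at most 50 iterations per IMF and 12 IMFs. These stop
criteria are pinned constants of the package so decompositions are
reproducible. The decomposition is additive by construction; every call is
covered by a reconstruction assertion (max error ≤ 10^-8^ of the input
range).

`instantaneous_attributes()` uses the normalized Hilbert transform: an
amplitude envelope splined through the maxima of |IMF| (iterated up to three
times; the envelope is clamped to dominate the signal pointwise, because
spline undershoot between knots would otherwise push the normalized carrier
outside [-1, 1] and destabilize the iteration), phase from the analytic
signal of the normalized carrier, and frequency as the phase gradient
clipped at zero. Stretches where the envelope falls below 10^-3^ of its
maximum are masked from frequency statistics rather than clipped to a floor:
the amplitude-weighted characteristic frequency
(`characteristic_frequency()`, Σaf/Σa) is robust to missing samples but not
to spikes. The phase convention places a crest ("upstate") at π/2 and a
trough ("downstate") at 3π/2; the raw Hilbert convention (crest at 0) is
also exposed.

IMF power (`imf_power()`) is the mean squared instantaneous amplitude as a
percentage of the total. IMFs slower than 10^-3^ Hz complete too few cycles
for circular statistics and are excluded from them by
`exclude_slow_imfs()` — but retained for reconstruction and for the
low-frequency regression bin, which deliberately targets exactly that band.

`phase_preference()` is the weighted first trigonometric circular moment:
with m the z-scored movement metric, active epochs use weights max(m, 0) and
quiescent epochs max(-m, 0); the moment's argument is the preferred phase
and its modulus the coupling strength in [0, 1]. The weights are the signed
sample values themselves (not ranks), with the opposite sign zeroed.

A known limitation of plain (non-ensemble) sifting: under broadband noise a
slow tone can be torn across two adjacent IMFs ("mode mixing"). Ensemble
EMD, the standard remedy, is out of scope here; the tone-separation tests
therefore use clean two-tone fixtures, and decompositions of noisy sessions
are validated through quantities that are robust to mixing (power sums,
max-power IMF phase statistics, band-binned regressions).

## Bouts and behavior

`detect_bouts()` smooths the z-scored metric with a 20-sample (1 s) moving
average and marks onsets where the smoothed trace reaches ≥ 0 after at least
4 s strictly below 0 — the threshold is exactly 0 SD, no hysteresis.
`cluster_bouts()` runs k-means (k = 2, 10 restarts, seeded) on the raw
0–4 s post-onset metric windows; the higher-energy cluster is "large". The
windows are used unscaled by default (a scalar peak-amplitude feature is a
config switch), since the window captures the small/large extent of a
movement.
`align_and_baseline()` re-expresses each bout window as a z-score against
its own [-3, -1] s pre-onset baseline — the methods phrase "1–3 s before
initiation" and the figure phrase "-3 to -1 s" denote the same interval.

Behavior likelihood rows are smoothed per class with a 4 s moving average
before the per-frame argmax (`labels_from_likelihoods()`); exact ties keep
the previous frame's label (first frame: first class in canonical order).
`transition_matrix()` counts label changes (self-transitions excluded) and
row-normalizes; `align_to_transitions()` and `behavior_means()` provide the
transition-aligned and per-class summaries.

## Statistical models

* `session_correlation()`: Pearson r over all aligned samples, with an
  optional epoch mask (e.g. non-locomotor periods); repeated sessions are
  averaged per subject by `subject_mean_correlation()`.
* `crosscorr_lag()`: normalized cross-correlation over ±10 s; negative lags
  mean photometry precedes movement. `iqr_outliers()` applies the 1.5 × IQR
  rule across subjects.
* `lmm_aic_trio()`: three maximum-likelihood mixed models — behavior fixed
  effect with random intercept; movement fixed effect with random slope;
  both with random intercept and slope — compared by AIC. ML rather than
  REML because the fixed-effect structures differ. Singular fits are
  reported and retained.
* `glucose_preprocess()`: linear interpolation of missing telemetry,
  resampling onto the photometry grid, 10 min moving average, first
  difference × fs as the derivative (mM/s). Linear rather than Fourier
  resampling: telemetry at 0.1 Hz is far below Nyquist for the glucose
  dynamics of interest, and Fourier resampling rings on a non-periodic
  infusion rise.
* `imf_multiplex_fit()`: per-IMF OLS on the z-scored glucose derivative and
  z-scored movement (z-scoring makes the two weights comparable across
  subjects); `bin_multiplex_weights()` averages them per subject within the
  0.01–0.1 Hz and < 10^-3^ Hz bands. The statistical family for the band
  tests is two (glucose, movement) per bin, Bonferroni-corrected.
* `percentile_interaction()`: photometry ~ movement × within-session
  percentile rank of the 10-min-smoothed glucose; the interaction asks
  whether movement encoding scales with glycemia.
* `pls_drop_one()`: two-component PLS regression, R² as the mean of a
  seeded fivefold cross-validation, and per-feature contributions
  `100·(1 - R²_partial,k / R²_full) / Σ_j (1 - R²_partial,j / R²_full)`,
  which sum to 100. If dropping any feature changes nothing (duplicated
  features), the symmetric limit — an even split — is returned; if R²_full
  ≤ 0 the contributions are undefined and flagged.
* `circular_regression()`: phase is encoded as (sin θ, cos θ), each
  component fitted against log10(frequency) with a kernel support-vector
  regressor (two single-output SVRs realize the multi-output fit; a loess
  alternative is exposed), predictions renormalized to unit length and the
  phase recovered by atan2 — continuous across the 0/2π wrap, evaluated on
  a 7-point log-frequency grid.

## Pupillometry

`fit_circle()` minimizes Σ(‖p−c‖−r)² with Nelder-Mead (objective relative
tolerance 10^-12^; the solution is guaranteed no worse than its
centroid/mean-distance initialization) over landmarks with confidence
> 0.8; frames with fewer than three such points (blinks) are invalid.
`pupil_traces()` interpolates invalid frames linearly in radius/center
space — interpolating the radius and deriving the area keeps the geometry
consistent; area-space interpolation is a config alternative — then derives
pupil size (πr², z-scored) and ocular movement (per-step center
displacement, z-scored). Displacement during interpolated spans is nonzero
by construction and identifiable through `interpolated_mask`.

## The synthetic-session generator

`generate_session()` produces the five inputs with controllable coupling:

* **Movement**: a shot-noise bout process. Inter-bout gaps are a 15 s
  refractory period plus an exponential, for 2 bouts/min by default; bout
  envelopes rise instantly and decay as a half-Gaussian (σ = 1 s), which
  concentrates movement-metric power in the 0.1–0.01 Hz band. Amplitudes
  are a bimodal small/large mixture (0.5 vs 3.0, 30% large). The refractory
  default matters: a large bout's kernel-convolved tail needs ~6 s to fall
  back below the z-mean, and the bout definition itself demands 4 s of
  sub-threshold quiescence, so shorter gaps would generate "bouts" that are
  undetectable under the package's own definition. Likewise the 2/min rate
  keeps the quiescent baseline shallow enough that a small bout crosses the
  zero threshold within the half-second alignment tolerance used by the
  recovery tests.
* **Photometry**: triple-exponential bleaching + gain × the band-limited,
  z-scored, kernel-convolved movement + gain × the smoothed glucose
  derivative + optional sinusoids + white noise. The movement coupling is
  high-passed with a 2 min moving-average complement (negligible gain below
  1 mHz): slow drifts in overall movement level are not written into the
  signal, which is precisely the band-separated multiplexing the analysis
  is meant to detect. The isosbestic channel shares the bleaching shape but
  never carries the movement signal — it is a motion-artifact control.
  White photometry noise is an assumption of convenience; the noise
  spectrum of real recordings is not modeled.
* **Glucose**: baseline 5.5 mM with a slow drift, an optional logistic
  infusion rise (3 mM over ~10 min), telemetry at 0.1 Hz with 5% missing
  samples to exercise interpolation.
* **Pupil**: eight landmarks on a slowly wandering circle with radial
  jitter; short low-confidence episodes emulate blinks.
* **Behavior**: a sticky 5-state Markov chain (~10 s dwell) whose states
  add class-specific movement floors (running highest), so photometry
  class-means track movement class-means.

Phase-locked sessions (`burst_phase` set) place bursts so that the **active-
epoch circular mean of the realized movement metric** sits at the requested
oscillation phase. Naively centering burst onsets at the crest fails in two
ways: threshold clipping skews the weighted mean of an instant-rise burst,
and the causal kernel tail makes the metric's above-zero support one-sided,
which separates the active and quiescent circular means by a structural
angle. The generator therefore self-calibrates in two passes against the
known oscillation phase and splits the structural asymmetry 0.4/0.6 between
the active and quiescent conditions (matching how tightly each is
interpreted downstream).

### Preset study conditions

`session_preset()` freezes one parameter set per analysis: `movement`
(default 20 min, 20 Hz), `bouts` (bout process only, no behavioral floor),
`phase` (40 min; photometry is a 0.0125 Hz oscillation plus noise, with
unimodal bursts locked to its crest — the movement copy is not additionally
injected, since the oscillation itself is the band activity under study),
`multiplex` (2 h at 2 Hz with an infusion at 30 min, so the session is long
enough to resolve sub-millihertz IMFs while staying cheap to decompose),
and `behavior` (20 min at 2 Hz, class-modulated movement driving photometry,
used in cohorts with per-subject gains for the mixed-model comparison).
The reduced sampling rates in the long conditions are a problem-size choice:
all the relevant dynamics sit below 0.1 Hz.

## What the synthetic tests do and do not show

Passing tests demonstrate that every operation recovers the known structure
it was pointed at — couplings, lags, phases, band assignments, bout times,
mixture labels — under the generator's assumptions: white noise, exactly
exponential bleaching, stationary coupling gains, a circular pupil. They do
not certify performance on real recordings, where noise is colored, bleach
curves are only approximately exponential, behavior classifiers and
landmark detectors have structured errors, and neural coupling drifts.
Headline effect sizes from real animals (e.g. a movement-photometry r of
0.68 ± 0.04) are properties of those data, not reproducible targets for a
simulation; the package's checks are therefore property-based.

## Reproducibility

All generator and analysis randomness is seeded (`with_seed` isolates the
global RNG state). `run_pipeline()` stamps every result bundle with an MD5
hash of its full configuration and of the outputs, and rejects unknown
configuration keys, so a result can always be traced to the exact parameter
surface that produced it.
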