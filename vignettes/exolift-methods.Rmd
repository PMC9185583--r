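---
title: "Assessing a passive lumbar exoskeleton from surface EMG and joint angles: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing a passive lumbar exoskeleton from surface EMG and joint angles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Passive lumbar exoskeletons redistribute part of the trunk-flexion load of
repetitive lifting to the legs. Whether they actually relieve the back — and
whether they slow the build-up of muscular fatigue over a work bout — is
assessed in the laboratory by instrumenting workers with surface
electromyography (sEMG) on the muscles of interest and inertial motion
capture on the joints, and comparing a standardised lifting task performed
with and without the device.

`exolift` implements that assessment as a reproducible pipeline for a
depalletizing protocol: a subject lifts 16 boxes per exercise at a 6-second
cadence, repeating the exercise for three box weights (7, 8, 9 kg) under
both conditions. Four muscles are monitored at 2000 Hz (erector spinae,
gluteus medius, quadriceps femoris, semitendinosus) and joint angles at
100 Hz.

## Signal conditioning and per-lift segmentation

Raw sEMG is conditioned with a zero-phase Butterworth band-pass, 20–200 Hz,
design order 10, applied forward and backward (`bandpass_filter()`). The
zero-phase contract matters because segment boundaries are defined on the
filtered signal: any group delay would bias every boundary. Edge transients
are controlled by even-reflection padding of at least three filter lengths
and three periods of the low cut-off. We read "order 10" as the design
order of the single-pass band-pass; since a Butterworth band-pass obtained
from the low-pass transform has even order, the alternative convention
(order 10 spread across the two passes) is only constructible for orders
divisible by 4 and is exposed as `order_convention = "overall"`.

Lift marks come from the motion capture (the lift's mechanical phase).
Because myoelectrical activation precedes mechanical activation, every
start mark is relocated one second earlier (`shift_marks()`); a shifted
start is clamped at the previous lift's end and flagged. Refinement then
uses a combined intensity trace (`combined_intensity()`): the sum over
channels of the squared 0.1-s frame RMS, each channel normalised by its
whole-exercise RMS so no channel's gain dominates. Within each slice the
reference level `H` is the mean of intensity values above 85% of the slice
maximum, the detection threshold is 15% of `H`, and the refined segment
runs from the first to the last frame at or above threshold
(`refine_marks()`).

Two readings of "above 85%" are defensible — above 85% of the slice
maximum, or above the 85th percentile. We default to the maximum-referenced
reading (it is scale-free and matches the rule's own reference to "that
value"); the percentile reading is available via `upper_mode =
"percentile"`. The historical final step of visual mark correction is
replaced by an exported review table with flags (e.g. a slice whose every
frame clears the threshold); nothing in the pipeline is interactive.

## Activation and fatigue parameters

For each of the 16 segments and each muscle (`extract_features()`):

* **VRMS** (µV): root-mean-square amplitude, the activation proxy.
* **TZC** (%): sign flips relative to segment length (each flip counts
  `2/N × 100`). Zero samples inherit the neighbouring non-zero sign so
  quantised baselines do not double-count flips.
* **FMN, FMD** (Hz): mean and median power frequency, averaged over the
  windows of a non-overlapping 0.5-s spectrogram. Windows of 1000 samples
  are zero-padded to 2048 points, giving 1024 positive-frequency bins that
  span exactly 0–1000 Hz (bin width 1000/1024 Hz). The per-window averages
  are divided by the number of valid windows; windows with zero power are
  excluded and logged. The window is rectangular by default — the
  parameters are defined on raw spectrogram power — with Hann available.
* **FI**: the Dimitrov spectral fatigue index, the ratio of the order −1 to
  the order +5 spectral moments of the summed spectrogram (the spectral
  marginal) over the 20–200 Hz band. For a narrowband spectrum at `f0` the
  index equals `f0^-6`, so downward spectral shifts (fatigue) raise it
  steeply. The band is selected by physical frequency; a literal bin-index
  band (e.g. bins 41–410) is available via `index_band` for comparison
  with conventions that index bins directly, but note that with the
  1000/1024-Hz bin width those indices correspond to 40–400 Hz.
* **log(FIn)**: the logarithm (natural, by default; base 10 available, and
  the base is scale-relevant for percent effects, so it is recorded in
  output metadata) of FI normalised by its minimum within the exercise and
  muscle. The least-fatigued segment maps to 0 and the curve across boxes
  tracks fatigue build-up.

Spectral mean, median and the Dimitrov ratio are each cross-checked in the
test suite against independent brute-force summation oracles on random
spectra, and against closed forms (single tones, single-bin spectra, the
`2^6` shift law).

## Effect estimation

For each variable (VRMS, TZC, FMN, FMD, log(FIn)) and muscle, the effect of
the exoskeleton is estimated with a linear mixed model
(`fit_mixed()`, REML via lme4):

```
y ~ exo * box + weight + (1 | user)
```

with box position and weight as categorical fixed effects and a per-subject
random intercept. The subject intercept is justified by the intra-class
correlation (`icc()`), the fraction of variance attributable to
between-subject differences, which is around 50% for the amplitude
variables in the synthetic default study. Condition means are adjusted
means averaging uniformly over the other fixed factors (`marginal_means()`,
computed with emmeans and equal weights; the per-box condition curves come
from the `exo:box` grid). The headline quantity is the percent change
`(mean_exo − mean_noexo) / mean_noexo × 100` — negative means a reduction
without the device's assistance — with a delta-method 95% half-width on the
percent scale and an asymptotic two-sided p-value for the condition
contrast (with 768 observations per fit the normal and t references are
indistinguishable).

Condition contrasts form a multiple-testing family; the family-wise error
is controlled by Holm's step-down method (`holm_adjust()`, via
`stats::p.adjust`). The family is the per-variable set of muscle contrasts
by default; a single all-contrasts family is available, and the choice is
recorded in the output.

## Range of motion

Joint-angle traces are summarised per coordinate by the five percentiles
P5–P95 over the whole exercise (linear-interpolation quantiles), and the
percentile range of motion `PRoM = P95 − P5` (`rom_percentiles()`,
`prom()`). Per-exercise statistics are averaged over the three weights
within subject and condition — the pooling is a package choice, recorded
here — and conditions are compared with a two-sided paired t-test across
subjects (`compare_conditions()`; an unpaired mode exists). Constant
paired differences are reported as degenerate rather than given a
p-value.

## The synthetic study generator

No public recordings exist for this protocol, so validation rests on a
generator (`synth_config()`, `generate_emg()`, `generate_mocap()`) whose
defaults are the study conditions: 8 subjects × 2 conditions × 3 weights ×
16 boxes at a 6-s cadence, 2-s bursts, 2000/100 Hz.

Each lift is band-limited noise under a raised-cosine-tapered envelope
(0.1-s ramps). The noise is synthesised in the frequency domain — flat
magnitude in a 40-Hz band around the muscle's centre frequency, random
phases — so its spectrum is exactly band-limited and symmetric about the
centre; as a sum of many independent-phase sinusoids the series is
asymptotically Gaussian. The burst is rescaled so its RMS equals the
realised per-burst target exactly, which makes the ground truth sharp: the
amplitude model is

* base amplitude per muscle (60/40/50/45 µV) × a lognormal subject factor,
* × `(1 + 0.20 · ramp)` fatigue drift from box 1 to 16 (centre frequencies
  correspondingly compress by 10%),
* × `(1 + effect_m)` under the exoskeleton (−8/−5/−4/−14% by muscle,
  following the sign and order of magnitude of reported lumbar-exoskeleton
  assessments; a calibration of the generator, not ground truth about any
  particular device),
* with both fatigue slopes slowed by 25% under the exoskeleton for the
  three assisted muscles (0 for the quadriceps),
* × `(1 + 0.05 · (kg − 7))` per box weight,
* × a per-burst lognormal residual (log-sd 0.15).

The subject log-sd is `0.15 · sqrt(share/(1 − share))`, so the
between-subject share of log-amplitude variance equals
`subject_variance_share` (default 0.5) by construction; the residual field
exists precisely because a variance share is only defined relative to a
within-subject variance. A 2-s lead-in of baseline noise (1 µV white)
guarantees the 1-s mark shift never underflows. Motion traces carry one
half-cosine excursion per lift, starting 0.5 s after the EMG burst onset
(activation precedes movement; the coarse marks are these mechanical
intervals quantised to the 100-Hz grid), with amplitude growing by pallet
row and, under the exoskeleton, scaled by the configured per-coordinate
range effects (−39% lumbar rotation, −3% lumbar flexion/extension by
default).

Because burst RMS is normalised, simulation studies of the mixed model do
not need waveforms at all: `simulate_feature_frame()` draws the same
per-burst amplitudes directly from the model. The replicate-heavy checks
(effect-recovery coverage over 200 replicates, null rejection rate over
500, ICC recovery over 50) use this fast path; the waveform path is
validated separately (filter contract, segmentation recovery over 20
generated exercises, spectral-centre and burst-RMS ground-truth checks,
fatigue-direction signatures on fully synthesised studies). The two paths
share the amplitude model by construction.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: motor-unit structure, inter-channel crosstalk,
movement artefacts and electrode noise beyond a white floor, non-stationary
cadence, heteroscedastic subject-by-condition interactions, and any
relationship between the EMG and the motion trace beyond timing. Recovery
results certify the pipeline's correctness, not the field validity of any
particular effect size.

## Numerical choices and degenerate inputs

* Intensity frames and spectrogram windows are non-overlapping with
  trailing partial frames dropped.
* The median-frequency bin is the first bin at or past half the cumulative
  power.
* A channel with zero total RMS, a slice with flat intensity, a segment
  shorter than one spectrogram window, a zero-power analysis band, and a
  zero baseline mean are each handled as distinct, named errors or flagged
  missing values — never silent.
* Mixed-model fits with empty condition-by-box cells degrade to the
  additive model with a warning; non-convergence is flagged, never
  replaced by a fallback.
* Percent-change intervals use the delta method on the contrast scale at
  95%.

## Problem sizes used in the checks

The default test run generates single exercises or small studies (2–4
subjects, 4–8 boxes) for unit checks, 20 full-rate exercises for
segmentation recovery, one 8-subject fully synthesised study for the
fatigue-direction and range-of-motion checks, and 200/500/50 model-level
replicates for coverage, null calibration and ICC recovery. These sizes
give Monte-Carlo error comfortably below the tolerances they are checked
against.

## Known limitations

* The Holm family definition and the weight-pooling rule for range of
  motion are conventions; both are configurable and recorded in outputs.
* The asymptotic p-values are calibrated for the default design size; for
  much smaller designs a finite-sample reference would be preferable.
* The literal bin-index band for the Dimitrov index reproduces a published
  indexing convention that is inconsistent with the 1-kHz bin mapping; it
  exists for comparability, not as a recommendation.
* Composite ergonomic risk indices, electrode placement, inverse
  kinematics and metabolic or subjective measures are out of scope.
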