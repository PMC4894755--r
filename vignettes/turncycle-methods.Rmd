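---
title: "Methods: quantifying side-specific motor output in a turning insect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying side-specific motor output in a turning insect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turncycle)
```

## The analysis problem

When an insect turns, the legs on the inside and outside of the curve do
different jobs, and the motor networks driving them receive different
descending and sensory signals. The measurements that expose this are all
derivative: step periods segmented from tarsal-contact recordings, EMG and
extracellular nerve activity conditioned into envelopes, responses to
controlled load stimuli on the leg's strain sensors (campaniform
sensilla), the phase coupling of motoneuron activity to the stepping
rhythm of a neighbouring leg, and the cycle frequency of the slow
alternating rhythm that the thoracic central pattern generators (CPGs)
produce under pilocarpine. `turncycle` implements this analysis chain as
composable, tested functions, together with a synthetic-data generator
whose ground truth makes every stage verifiable by parameter recovery.

## Step cycles and periods

A step cycle is anchored at stance onset: it runs from one touchdown to
the next, with the lift-off in between splitting it into stance and swing.
`segment_steps()` pairs each touchdown with the unique lift-off before the
next touchdown; intervals with zero or two lift-offs are rejected and
counted rather than repaired, since such patterns indicate detection
errors. Cycle phase is the linear map `(t - touchdown)/period` onto
[0, 1). Two design choices were genuinely open:

* **Pause handling.** Walking bouts contain pauses that are not steps.
  Cycles whose period exceeds the bout mean by more than 5 sample SDs are
  flagged and excluded from period statistics. The threshold is
  deliberately loose: at the preset period distributions a true step
  essentially never reaches it.
* **The period comparison test.** The inside/outside comparison is a
  two-sided Welch t-test on per-sequence mean periods (a rank-sum
  alternative is available via `method = "wilcox"`). Per-sequence means
  are the right unit because sequences, not steps, are exchangeable
  between conditions; Welch avoids assuming equal variances, which the
  inside and outside distributions clearly violate.

Event detection from the contact signal follows the signal's physics: the
tarsal current switches on at touchdown, so touchdown is a threshold
crossing (sub-sample timing by linear interpolation across the crossing
samples), while lift-off — slowed by lubricant tearing — is defined as the
time of the steepest ascending slope within the stance-to-swing
transition. Slope ties are resolved to the earliest sample, with a small
relative tolerance so that exactly linear ramps do not break ties on
floating-point noise.

## Signal conditioning

EMG and nerve traces are rectified and smoothed. Two smoothers are
provided because the analyses use both: a boxcar averaging `[t - T, t + T]`
with `T = 0.05` s, and a running Gaussian average of total width 100 ms
for the load-response envelopes. "Width" of a Gaussian window is
ambiguous (support, FWHM, or sigma); we fix *total kernel support* =
`width`, truncated at ±`width`/2, with `sigma = width/4`, which matches
common practice for running-average windows and keeps >95 % of the
Gaussian mass inside the support. At the trace edges both smoothers
renormalize the truncated window by the actual sample count; constants are
therefore fixed points everywhere, and interior samples equal a plain
convolution. (Edge renormalization does *not* preserve the trace mean in
general — only constants enjoy that — so tests assert the convolution
identity in the interior and exact constancy for constants.)

Antagonist crosstalk is removed by the capped-rescale rule: the agonist
envelope is min-max normalized to [0, 1], the antagonist envelope is
rescaled to [0, 0.5] (the cap reflects the smaller size of antagonist
leakage), subtracted pointwise, and negatives are clipped to zero since a
rectified envelope is non-negative by definition. A constant antagonist
rescales to zero and leaves the agonist unchanged; a constant agonist
segment normalizes to all zeros. Per-step normalization (min 0, max 1)
uses the same degenerate-segment convention.

## Load-stimulus responses

Responses of the retractor/protractor motoneuron pools to a load stimulus
are scored two ways, mirroring the two normalizations in use:

* **Response magnitude**: the maximum of the conditioned retractor
  envelope in the 150 ms window after the stimulus, divided by the mean of
  the corresponding maxima over *control* stimuli (those delivered in
  quiescence, operationalized as stimuli with no touchdown within one mean
  period on either side).
* **Michelson contrast**: `(post - pre)/(post + pre)` of mean envelope
  activity in 100 ms windows around the stimulus, bounded in [-1, 1],
  positive when activity increases. The convention follows the
  interpretation "values above 0 indicate an increase after stimulation";
  0/0 is defined as 0 because a silent trace shows no response.

Classification into retractor activation (`RET_ACT`), protractor
activation with retractor termination (`PRO_ACT`), and no response
(`NONE`) thresholds the two contrasts at ±0.5. No numeric criterion
separating "activation" from "no response" exists in the literature this
emulates; ±0.5 cleanly separates the generator's step transients from its
noise floor and both thresholds are exposed as arguments so users can
calibrate them against their own recordings. Phase dependence of a class
is assessed by attaching each stimulus's step-cycle phase and computing a
circular mean vector with a Rayleigh test at the conventional 0.05 level
for this analysis.

## Circular statistics

Phases live internally on [0, 1) as cycle fractions; degrees appear only
at the interface (conversion ×360). The weighted mean vector is
`R e^{i mu} = sum(w e^{i theta}) / sum(w)`; spike-based polar vectors
weight each spike equally. The Rayleigh p-value uses the standard
second-order series approximation in `Z = nR^2`, clamped into (0, 1],
with significance flagged at 0.005 for polar vectors; for n < 4, where
the series is unreliable, a Monte-Carlo uniform null (10^5 draws under a
fixed internal substream) is used instead. The approximation's empirical
type-I error at the 0.005 level, measured over 10^4 uniform samples of
n = 50, falls within [0.003, 0.008] (asserted in the test suite). For
non-uniform weights the p-value uses the effective sample size
`(sum w)^2 / sum(w^2)`; it is exact only in the equal-weight case.

## Rhythm analysis

Burst detection uses a maximal-run criterion: inter-spike intervals at
most `max_isi` (default 0.2 s) with at least `min_spikes = 3` spikes.
The defaults separate the slow rhythm's burst regimes (0.27–1.16 Hz,
within-burst firing tens of Hz) from tonic activity; both are arguments.
Cycle frequency is the inverse mean inter-onset interval within the
analysis window — robust below ten cycles, where spectral estimates are
not. Quiescent versus stepping frequencies are compared with a paired
t-test across animals (each animal contributes one pair). Antagonist
alternation is quantified by a lag-wise Pearson cross-correlation
(correlating the overlapping segments at each lag), which is scale-free
and shows alternation as a dip at lag 0 with peaks near half the cycle
period.

## What the generator emulates — and what it does not

The generator's defaults are the study conditions: step periods Normal
(0.83 ± 0.21 s FL-inside, 1.21 ± 0.37 FL-outside, 0.76 ± 0.15 ML-inside,
1.13 ± 0.28 ML-outside, truncated at 0.1×mean so periods stay positive),
duty fraction 0.6; inside-mode spike trains as inhomogeneous Poisson
processes (by thinning) with von Mises rate profiles peaking at 270°
(protractor) and 90° (retractor), concentration 4 and base rate
25 spikes/s; outside-mode tonic firing with a 3:1 retractor bias (the
source reports only "strongly reduced"/"generally tonic"; the ratio is an
argument); slow-rhythm frequencies 0.27 Hz quiescent and 1.16 Hz during
stepping, with 5 % period jitter and cycles truncated at regime
boundaries; load-response class probabilities 0.712/0.10/0.188 — the
no-response rate 0.188 is the reported average, the protractor-activation
rate 0.10 is fixed inside the reported 2–25 % per-animal range, and the
retractor rate is the remainder — with no-response stimuli placed at von
Mises phase (mean 0.89 cycles, concentration 4) and at most one stimulus
on every other cycle so neighbouring analysis windows cannot collide.
Load-trial envelopes are a 0.5 baseline with 150 ms step transients of
amplitude 4.5 and Gaussian noise (SD 0.05); stimulus ramp kinetics are
unreported in the source, so the transient is a plateau whose duration is
an argument. Control stimuli are placed in a quiescent block *after* the
walking bout (event times are non-negative by contract, which rules out a
pre-roll).

The generator is deliberately idealized: envelopes are flat outside
transients (no step-locked background modulation, which in real data
confounds contrast windows near touchdown), spike trains have no
refractory period, crosstalk is linear and stationary, and noise is
Gaussian and white. Passing recovery tests therefore demonstrates that
the *analysis* is correct and calibrated under the stated statistical
structure — not that the pipeline is robust to every artefact of real
recordings (electrode drift, movement artefacts, non-stationary
crosstalk). The classification thresholds in particular are
generator-matched defaults, not universal constants.

## Problem sizes and numerical choices

Recovery analyses use 500 step cycles per preset (mean periods then
recover within 3 SE), 300 cycles for phase peaks (circular means within
5°), 120 s rhythm records (~30 quiescent or ~70 stepping cycles), and 500
load stimuli (class fractions within 3 binomial SE, no-response phase
within 0.03 cycles). Smoothing is exact convolution (no FFT), event times
are sub-sample by linear interpolation, ties resolve to the earliest
sample, and every generator accepts an integer seed with the contract
that identical configuration + seed gives bit-identical output; generator
functions save and restore the caller's RNG state.

## Worked example

```{r example}
run <- run_experiment("inside-walk", seed = 7, n_steps = 120)
run

pilo <- run_experiment("pilocarpine", seed = 7, duration = 60)
c(quiet = pilo$summary$freq_quiet, stepping = pilo$summary$freq_stepping)
```

## Known limitations

* Classification assumes conditioned envelopes and generator-scale
  contrasts; real data need threshold calibration.
* The no-response phase analysis needs at least 8 class members with
  defined phases; below that the result is flagged, not tested.
* Cross-correlation is O(lags × samples); for hour-long records at high
  rates, downsample first (e.g. via `spikes_to_rate()`).
* The weighted Rayleigh p-value is approximate (effective-n plug-in).
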