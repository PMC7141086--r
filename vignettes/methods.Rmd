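---
title: "Detecting hazard-evoked pupil dilations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hazard-evoked pupil dilations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilcascade)
```

## The problem

A sudden hazard elicits a stress response whose autonomic signature
includes a rapid dilation of the pupil: onset within 200–350 ms of the
stimulus, peak response between 500 ms and 1 s, and a gradual, often
oscillatory return to baseline over a total span of 2–2.5 s. In a
naturalistic recording (here: a 40-minute session sampled at 25 Hz by a
head-mounted eye tracker) this transient is buried under slow
non-stationary drift of the mean pupil size, spontaneous slow
fluctuation (hippus), blinks and tracking losses, gross detection
failures, and sample-level measurement noise. A plain threshold on pupil
size does not work; the package implements a cascade that does:

1. **Artifact rejection and QC** — blink/tracking-loss removal with a
   2-sample margin, a 10 % relative-jump rule, a 3-SD statistical
   outlier rule, linear gap interpolation, a 30 s acclimation trim, and
   exclusion of trials with less than 75 % valid data.
2. **Wavelet detrending** — the slow trend is the level-9 db4
   approximation (periods longer than ~40 s at 25 Hz) and is subtracted.
3. **Candidate peak detection** — local maxima at negative-going zero
   crossings of the smoothed first derivative of the (lightly smoothed)
   detrended signal, gated at 1.5 trial standard deviations; each
   candidate is characterized by a least-squares parabola over a 2.5 s
   window and its full width at half maximum.
4. **Wavelet features** — a 75-sample window (±1.5 s) around each
   candidate is decomposed with db4 wavelets to level 4; amplitude, mean
   and area of the A4 reconstruction plus the relative energies of the
   D1–D4 detail bands give a 7-component feature vector.
5. **Classification** — an RBF-kernel SVM separates hazard-evoked from
   spurious candidates, trained with minority oversampling and evaluated
   by leave-one-subject-out cross-validation (LOSO).

The package also ships a synthetic trace generator with known ground
truth, so the whole cascade is testable end to end without access to
driving-simulator recordings.

## Scale conventions

All detection thresholds are scale-free: the jump rule is relative, and
the outlier and amplitude gates are in units of per-trial standard
deviations. The pipeline therefore works identically on pupil diameter
or pupil area traces; the unit is carried only as metadata.

## The discrete wavelet machinery

No wavelet transform was available in the target environment's R
libraries, so the package implements the orthogonal Daubechies filter
bank directly: the analysis low-pass/high-pass pair applied successively
with downsampling by 2, and the exact synthesis inverse. Internally the
signal is extended (symmetric half-point reflection by default, periodic
optionally) to the next multiple of $2^J$ and transformed periodically,
which makes the transform exactly invertible for every input length and
boundary mode. Under periodic boundaries on dyadic lengths the transform
is orthonormal, so coefficient energy equals signal energy (Parseval);
the test suite checks both properties to $10^{-8}$ relative error and
verifies the coefficients against a brute-force convolution-and-
decimation oracle built from the published db4 taps.

Band ordering follows the finest-first convention: `D_1` is the
highest-frequency detail band. At 25 Hz the level-4 bands are
approximately D1 = 6.25–12.5 Hz, D2 = 3.1–6.25 Hz, D3 = 1.6–3.1 Hz,
D4 = 0.78–1.6 Hz, A4 = 0–0.78 Hz; the 1–2 s time scale of evoked
dilations is why decomposition depth 4 is used for features.

**Detrending depth.** The trend level is configurable and defaults
to 9: the A9 band at 25 Hz contains periods longer than roughly 40 s,
which captures drift over minutes without touching the 2–2.5 s
transients. Any residual constant left by boundary effects of the
approximation is folded back into the trend so the detrended signal is
exactly zero-mean.

## Detection design

**Signal smoothing before detection.** Candidate detection operates on
the filtered-and-smoothed detrended signal: a zero-phase Gaussian kernel
with SD 10 samples (400 ms) is applied before the derivative. The kernel
passes the band of the evoked transients (main lobe below ~0.3 Hz)
essentially intact while suppressing sample-level tracker noise, whose
extrema would otherwise dominate the candidate list: without it a
40-minute trace with 2 % white measurement noise yields on the order of
a thousand above-gate extrema, two orders of magnitude more than real
recordings produce. With the default kernel the generator's traces yield
roughly 120–130 candidates per 40-minute trace, the order of magnitude
reported for real drives. Extrema within the kernel's support of the
trace edge are discarded as padding artifacts.

**Amplitude gate.** The 1.5-SD gate uses the standard deviation of the
full smoothed detrended trial — a single-pass, trial-global reference in
the same spirit as the outlier rule. The gate applies to the raw
(smoothed) extremum value, not the parabola-fitted height.

**Parabola and FWHM.** The least-squares quadratic is fit over ±1.25 s
around the peak. FWHM needs a baseline; the package uses the minimum of
the fitted parabola over the window, giving
$\mathrm{FWHM} = 2\sqrt{h/(2|c|)}$ with $h$ the fitted height above that
baseline and $c$ the quadratic coefficient. Candidates whose fitted
vertex is not a maximum are discarded. Edge-truncated windows are used
if at least 5 samples remain.

**Only maxima.** Dilation peaks are the objects of interest;
constriction minima are ignored.

## Feature and labeling choices

Features are computed from the unsmoothed detrended window: the A4
reconstruction is itself a 0.78 Hz low-pass, so amplitude, mean and area
are stable against sample noise, while the D1–D4 relative energies
retain the fast-noise signature that helps separate spurious peaks.
"Area" is the trapezoidal integral of the A4 reconstruction above its
window minimum ("mean" is the plain A4 average), computed in the time
domain because the features are defined on the A4 time course. A window
that would extend beyond the trace drops the candidate — never silent
zero-padding.

A candidate is labeled a true hazard response iff its peak time falls
within 2.5 s after an annotated onset (the expected duration of the
evoked response); per event only the earliest matching candidate is
labeled hazard, each event matches at most once, and unmatched events
are carried through the evaluation as missed detections.

## Classifier

The 7 features are z-scored with training-fold statistics (they mix
units; a zero-variance feature standardizes to 0 with a warning). The
minority class is balanced by random duplication to parity inside each
training fold only; the held-out subject is never oversampled, and
training rows are put in a canonical order first so results do not
depend on how the caller ordered subjects. Scores are oriented so
positive means hazard, with the class decision at threshold 0 by
default; the ROC sweeps all observed scores.

The paper-level method does not specify SVM hyperparameters. The
package's defaults are `C = 10` and the `1/(p \cdot \mathrm{var})`
kernel width: they were selected by leave-one-subject-out model
selection on two disjoint synthetic cohorts during development and are
deliberately fixed rather than re-searched per fold — a nested in-fold
grid search multiplies runtime by the grid size times the inner-fold
count and changed held-out performance only marginally on the synthetic
cohorts. Both parameters remain user-settable.

**Two evaluation views.** Sensitivity can be counted over candidates
(matched candidates classified correctly) or over events (an annotated
event with no candidate at all is a false negative too). Both are
reported: the event-level view is the quantity of scientific interest
(was the hazard perceived?), the candidate-level view is what the
classifier actually sees. Zero-denominator metrics are reported as
undefined, never as 0.

## The synthetic generator

`generate_trace()` builds baseline + drift + hippus + white noise +
evoked transients, then overwrites blink runs (size 0, invalid) and
injects isolated gross outliers. Conditions follow the recording setup
the cascade targets: 2400 s at 25 Hz, 9 events per trace, baseline 4.0
(a 4 mm pupil).

Defaults, and why:

* **Drift**: sum of three sinusoids with periods 600/300/120 s, random
  phases, total amplitude 0.3 × baseline — non-stationary trend over
  minutes.
* **White noise**: SD 0.02 × baseline, the sample-level jitter of a
  video eye tracker.
* **Hippus**: AR(1)-filtered noise with a 6 s time constant
  (power concentrated below ~0.1 Hz), SD 0.0125 × baseline (~0.05 mm) —
  slow spontaneous oscillation, the main source of event-like spurious
  peaks. Amplitude and bandwidth are free parameters of the generator;
  they were set so that spurious-candidate counts per trace land at the
  order of magnitude observed in real recordings.
* **Events**: onset latency U(0.2, 0.35) s, time-to-peak U(0.5, 1.0) s,
  span U(2.0, 2.5) s; amplitude 2.5 × the non-event SD (noise + hippus),
  so the 1.5-SD gate is exercised at a known contrast. The paper-level
  method reports no evoked amplitude; 2.5 SD is a generator choice.
  The kernel rises along a smooth monotone (smootherstep) ramp and
  returns along a raised cosine modulated by geometrically decaying
  ripple waves (2 waves, decay 0.5 by default) — "rapid dilation,
  gradual oscillatory return". The kernel is continuous, peaks at
  exactly 1, and is below 0.05 at the end of the span.
* **Blinks**: Poisson 12/min, uniform 2–5 samples long, written as
  zero-size invalid runs. **Outliers**: Poisson 2/min, isolated samples
  at least 3 trial SDs off the local level.
* **Determinism**: one RNG stream per trace, fully determined by `seed`;
  the caller's RNG state is untouched.

What the generator does *not* emulate: luminance-driven pupillary light
reflex responses (the simulated environment's brightness is nearly
constant), eyelid-occlusion geometry during partial blinks, saccade- or
gaze-position-dependent size artifacts, and non-Gaussian heavy-tailed
tracker noise. Passing end-to-end tests on synthetic data therefore
demonstrates internal consistency of the cascade under the stated noise
model, not field performance on arbitrary eye trackers.

## Numerical choices and degenerate inputs

* Jump rule: the reference is the last still-valid sample, so one bad
  sample cannot cascade; the relative difference uses the reference as
  denominator.
* Outlier rule: mean/SD computed once over blink/margin/jump-cleaned
  samples (a single statistical pass, not iterative re-estimation), and
  the deviation is two-sided — tracker failures produce both too-large
  (iris instead of pupil) and too-small sizes.
* QC boundary: 75 % is inclusive (exactly 75 % valid is kept).
* Interpolation: interior gaps linear between nearest valid neighbors;
  boundary gaps constant-extended. Idempotent by construction.
* Constant signals: no candidates (guarded against FFT smoothing
  residue); zero-energy windows report all relative energies as 0.
* Ties in event matching resolve to the earliest candidate; equal-onset
  events keep their input order (stable sort).
* Trials shorter than the trim window, decomposition levels deeper than
  the signal allows, and annotations whose subjects do not match the
  traces all fail fast with informative errors.

## Problem sizes used in the automated checks

The end-to-end recovery check runs 5 independent cohorts of 8 subjects
with full-length (40-minute) traces and 9 events each — 360 events and
roughly 5 000 candidate decisions — and requires pooled event-level
sensitivity ≥ 0.8, candidate-level precision ≥ 0.7, and 90 % of matched
detections within ±0.5 s of the true peaks. Unit-level properties
(Parseval, perfect reconstruction, oracle agreement, FWHM, labeling,
ROC/AUC identities) run on hundreds of randomized small cases under
fixed seeds.

## Known limitations

* LOSO with 8 subjects leaves per-cohort metrics noisy; single-cohort
  event sensitivity varies by ±0.1 around its mean. Conclusions should
  pool cohorts (the acceptance checks do).
* The earliest-match labeling rule can transfer a label to a spurious
  candidate that precedes the true peak inside the matching window;
  with the default smoothing this affects ~1–2 % of events.
* Overlapping evoked responses are out of scope (no multi-peak
  deconvolution), as are gaze-position features and any fusion with
  other physiological channels.
* The classifier's operating point is the balanced-training default;
  applications preferring fewer misses at the cost of more false
  positives should sweep `decision_threshold` along the reported ROC.
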