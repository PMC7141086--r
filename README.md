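# pupilcascade

Detection and classification of hazard-evoked pupil dilation events in
noisy pupillometry time series.

## What it does, and for whom

A sudden hazard — say, a looming emergency during a drive — triggers a
stress response that dilates the pupil: onset within 200–350 ms, peak
between 0.5 and 1 s, and a gradual, often oscillatory return over
2–2.5 s in total. Researchers who record pupil size in naturalistic
settings (driving simulators, field eye tracking) can in principle read
hazard *perception* straight off this signal — independently of whether
the subject reacted behaviorally — but the transient is buried under
drift, hippus, blinks, tracking failures and measurement noise, and
many spurious dilation peaks look superficially similar.

`pupilcascade` implements the complete filtering-and-classification
cascade for this problem:

| stage | method |
|---|---|
| artifact rejection | blink/tracking-loss removal + 2-sample margins, 10 % relative-jump rule, 3-SD outlier rule, linear interpolation, 30 s acclimation trim, 75 %-valid QC gate |
| detrending | subtraction of the level-9 Daubechies-4 wavelet approximation (drift at periods ≳ 40 s) |
| candidate detection | zero crossings of the smoothed first derivative, 1.5-SD amplitude gate, parabola fit with FWHM over a 2.5 s window |
| features | db4 level-4 decomposition of a ±1.5 s window: amplitude, mean and area of the A4 component + relative energies of D1–D4 |
| classification | RBF-kernel SVM, minority oversampling, leave-one-subject-out cross-validation, ROC/AUC and per-subject candidate/false-positive tables |

A synthetic pupil-trace generator with known ground truth (drift,
hippus, blinks, outliers, and evoked transients with the physiological
time course above) makes every stage testable end to end.

The candidate feature vector, for a peak at time $t_p$ on the detrended
signal $x$: with $A_4$ the level-4 wavelet approximation of the window
$x[t_p \pm 1.5\,\mathrm{s}]$ and $E_j = \sum D_j^2$ the detail-band
energies,

```
amplitude = max(A4) − min(A4)
mean      = mean(A4)
area      = ∫ (A4 − min(A4)) dt
re_dj     = E_j / (ΣE_k + E_A4),   j = 1..4
```

## Worked example

```r
library(pupilcascade)

# four 15-minute synthetic subjects, six hazards each
sims <- lapply(1:4, function(s) {
  generate_trace(synthetic_params(duration = 900, n_events = 6, seed = s))
})

fit <- pupil_cascade(
  traces      = lapply(sims, `[[`, "trace"),
  annotations = lapply(sims, `[[`, "annotation")
)
summary(fit)
```

```
Dilation-detection cascade — leave-one-subject-out evaluation

Subjects: 4 accepted, 0 rejected by the 75% validity rule
Candidates: 126 (20 hazard-labeled, 106 noise)
<evaluation_report>
  candidate level: sens 0.750, spec 0.981, prec 0.882 (tp 15 fp 2 tn 104 fn 5)
  event level:     sens 0.625 (missed events counted as fn)
  ROC AUC: 0.960 over 126 candidates, 4 subjects

Per-subject candidate (D) and false-positive (F) counts:
 subject F  D
    SYN1 0 31
    SYN2 1 28
    SYN3 1 20
    SYN4 0 47
```

Reading this: the detector proposed 126 candidate dilation peaks across
the four drives (D per subject), of which 20 coincided with an injected
hazard. The cross-validated SVM kept 15 of those 20 (candidate-level
sensitivity 0.75) at only 2 false alarms (precision 0.88, F per
subject). Event-level sensitivity is lower (0.625) because 4 of the 24
injected events never produced a candidate at all on these short traces
— missed events are counted as false negatives, not ignored.
`plot(fit)` draws the candidate-level ROC; `predict(fit, new_trace)`
scores a new subject with the cohort model.

Individual stages are exported (`preprocess_trace()`, `dwt_detrend()`,
`detect_peaks()`, `extract_features()`, `label_candidates()`,
`loso_cv()`, …) and a thin command-line front end is installed at
`inst/scripts/pupilcascade.R` with `simulate`, `preprocess`, `detrend`,
`detect` and `run` subcommands.

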