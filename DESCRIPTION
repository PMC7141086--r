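Package: pupilcascade
Title: Detection and Classification of Hazard-Evoked Pupil Dilation Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A filtering-and-classification cascade for noisy pupillometry
    time series. Cleans raw pupil-size recordings (blink and tracking-loss
    removal, relative-jump and statistical-outlier rejection, linear gap
    interpolation, validity-based quality control), removes slow
    non-stationary drift by discrete wavelet (db4) approximation
    subtraction, detects candidate dilation peaks from zero crossings of a
    smoothed first derivative with an amplitude gate and parabolic
    full-width-at-half-maximum characterization, extracts a seven-component
    wavelet feature vector per candidate (A4 amplitude, mean and area plus
    relative D1-D4 sub-band energies), and classifies candidates as
    stress-evoked versus spurious with an RBF support vector machine under
    minority oversampling and leave-one-subject-out cross-validation. A
    synthetic pupil-trace generator with known ground truth makes the full
    cascade testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
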