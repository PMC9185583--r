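Package: exolift
Title: Surface EMG and Motion Analysis for Passive Exoskeleton Assessment
    in Repetitive Lifting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for laboratory assessment of passive lumbar
    exoskeletons during repetitive box-lifting tasks. Conditions
    multi-channel surface electromyography with a zero-phase Butterworth
    band-pass, segments exercises into per-lift bursts by combined-intensity
    RMS thresholding, computes activation and fatigue parameters (RMS
    amplitude, zero-crossing rate, spectrogram mean and median frequency,
    and the normalised logarithmic Dimitrov spectral fatigue index),
    estimates exoskeleton effects with per-muscle linear mixed models and
    Holm-adjusted marginal-mean contrasts, and summarises joint
    range-of-motion percentiles between conditions. Includes a synthetic
    multi-subject EMG and joint-angle generator with per-stage ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    emmeans,
    graphics,
    lme4,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
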