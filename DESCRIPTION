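Package: pupilhab
Title: Pupil Baseline Habituation Analysis for Speech-in-Noise Recall Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying physiological arousal and task habituation
    during auditory recall testing in noise. Implements the pupillometry
    preprocessing chain used with sentence-final word identification and
    recall (SWIR) sessions (eye selection, sliding-window blink detection,
    margin removal, linear interpolation, sentence- and participant-level
    validity filters), sentence/block pupil-baseline extraction and recall
    scoring, the adaptive procedures that set the individual signal-to-noise
    ratio (a weighted up-down HINT staircase and the SWIR training-list
    adjustment), and a linear mixed-effects workflow (predictor centering,
    maximal model, backward elimination of random then fixed effects, Type II
    Wald chi-square tests, marginal/conditional R-squared, variance inflation
    factors, median-split simple slopes and SNR-grid group contrasts). A
    synthetic-session generator produces complete eye-tracker datasets with
    known ground truth so that every stage is testable without access to raw
    laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    emmeans,
    optparse
Config/testthat/edition: 3
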