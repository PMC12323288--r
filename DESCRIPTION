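Package: vwpred
Title: Prediction-Efficiency Analysis for Visual World Paradigm Eye-Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for visual world paradigm (VWP) eye-tracking
    studies of predictive spoken-language comprehension. Converts raw 120-Hz
    binocular gaze samples into fixations (I-VT velocity classification with
    gap interpolation, fixation merging and minimum-duration filtering), bins
    fixations into a binary area-of-interest occupancy tensor, and provides
    the statistical engines used to quantify prediction efficiency:
    cluster-based permutation analysis of condition differences, growth curve
    analysis of log-gaze proportion ratios with orthogonal time polynomials,
    bootstrap divergence point analysis of predictive-looking onsets, and
    correlations of per-participant prediction indices with autism-related
    measures. Includes a synthetic cohort generator with known ground truth
    (counterbalanced quadruplet designs, two-group gaze processes, linked
    score tables) so every stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    withr,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    lmerTest,
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
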