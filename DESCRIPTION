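Package: gaitmark
Title: Gait-Cycle Template Matching, Automatic Labeling and Incremental
    Movement-Pattern Recognition from Wearable IMU Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recognizes movement patterns from a wearable sensor setup of
    two inertial measurement units (triaxial acceleration, pitch and roll
    each) and a footplate pressure channel. Segments recordings into gait
    cycles from foot-contact/foot-off pressure events, phase-normalizes
    cycles by cubic-spline interpolation and averages them into per-pattern
    templates, labels new cycles automatically by minimum dynamic-time-warping
    cost with a threshold-based data selection rule and adjacent-cycle
    transition suppression, and retrains window-level classifiers (QDA,
    polynomial-kernel SVM, a small convolutional network, and an LSTM) on
    the selected pseudo-labels. Includes the full evaluation layer
    (recognition error rate, row-percentage confusion matrix, success and
    data-selection rates, N-point majority vote, transition-success rule),
    cross-day experiment harnesses, and a synthetic multi-day gait generator
    that provides ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
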