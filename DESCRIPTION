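Package: mtrrp
Title: Multi-Threshold Recurrence Rate Plots for Time-Series Complexity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Recurrence quantification over a ladder of recurrence
    thresholds. Builds multi-threshold recurrence rate plots (MTRRP) from
    univariate time series via time-delay embedding, and derives three
    complexity metrics from the resulting curve: the Recurrence Rate
    Gradient (slope of the pre-plateau segment), the Recurrence Hurst
    (a Hurst-like exponent read off the curve through the model
    RR = alpha * (1 - RH * log eps)), and their product, the Recurrence
    Complexity. Includes exact-covariance simulation of fractional
    Brownian motion, adaptive fractal analysis (AFA) estimation of the
    Hurst exponent, a synthetic multi-channel EEG generator, Butterworth
    band-pass feature extraction over the conventional EEG bands, and a
    leakage-safe SVM leave-one-out classification protocol with a
    label-permutation null.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    e1071,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
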