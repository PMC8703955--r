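Package: rpfno
Title: Recurrence-Plot Encoding and Fourier Neural Operator Forecasting of
    Wearable Motion Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Short-horizon forecasting of wearable inertial (gyroscope and
    accelerometer) motion signals. Fixed-rate sensor streams are encoded as
    sequences of distance-only recurrence plots (and cross recurrence plots
    for two-sensor fusion), forecast about 0.6 seconds ahead by a Fourier
    neural operator whose spectral layers mix a truncated set of
    low-frequency modes, and decoded back to raw three-axis signals by an
    LSTM decoder. Includes a matched convolutional baseline, per-subject
    (personalized) training and cross-subject evaluation, mesh-invariance
    evaluation at unseen grid resolutions, an energy-score early-warning
    scheme for falls, and a synthetic quasi-periodic gait generator so the
    whole pipeline is testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
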