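Package: runkinetics
Title: Braking and Propulsion Force Estimation from Wearable Inertial
    Sensors During Running
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates the anterior-posterior component of the ground
    reaction force (braking and propulsion, in percent bodyweight) during
    running from body-worn inertial measurement units. Provides a
    synthetic multi-runner gait simulator with known ground truth, signal
    conditioning (zero-phase Butterworth filtering, force resampling,
    bodyweight scaling, grouped min-max normalisation, drift-corrected
    sagittal segment angles, cross-correlation synchronisation),
    force-threshold and prediction-based gait segmentation, a
    bidirectional LSTM sequence regressor with generalized training,
    individual fine-tuning and from-scratch individual training,
    leave-one-runner-out experiment drivers (stride-count sweep, sensor
    ablation), and impulse-versus-speed validation with inverse-variance
    weighted linear fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
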