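Package: elstm
Title: Ensemble LSTM Classifiers for Mortality Prediction from Clinical Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits ensembles of long short-term memory (LSTM) classifiers for
    binary outcome prediction (such as 28-day ICU mortality) from daily
    multivariate clinical time series. Base learners are trained on
    bootstrap-resampled patients and random variable subspaces and their
    sigmoid scores are averaged; class imbalance is handled by a
    negative-to-positive ratio weight in the cross-entropy loss. Includes
    linear-interpolation imputation and z-score normalisation preprocessing,
    last-observation-carried-forward padding for dynamic day-by-day risk
    prediction, AUROC/AUPRC and thresholded evaluation metrics, a repeated
    train/test-split experiment harness, and a synthetic cohort generator
    with class-dependent temporal drift for testing without access to
    restricted clinical databases. The LSTM forward pass, backpropagation
    through time and Adam optimiser are implemented in C++ for desk-scale
    CPU training.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
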