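Package: sersmix
Title: Multiplexed SERS Spectral Unmixing and Quantification with 1D
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and machine-learning analysis of multiplexed
    surface-enhanced Raman scattering (SERS) spectra of polycyclic aromatic
    hydrocarbon (PAH) pollutants in water. Provides a synthetic reference
    library and labelled mixture-spectrum simulator, Savitzky-Golay
    preprocessing, 1D convolutional neural networks for multilabel presence
    classification and contribution regression, geometric-mean threshold
    selection, Hill calibration curves with signal-to-noise limits of
    detection, contribution-to-concentration conversion, and a full
    evaluation toolkit (confusion matrices, micro/macro precision,
    sensitivity, specificity, NPV, F1, ROC-AUC, and spectral/concentration
    RMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
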