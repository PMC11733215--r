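Package: fmfusion
Title: Sensor Fusion for Automated Classification of Infant Fidgety Movements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multimodal classification of infant fidgety movements (FM+ vs
    FM-) from three synchronized sensor modalities: 2D pose key points,
    a 32x32 pressure-sensing mat, and six 6-channel inertial measurement
    units. Implements skeleton normalization (centering, rotation,
    scaling), center-of-pressure feature extraction, IMU channel
    preprocessing, a compact 1-D temporal convolutional network trained
    with Adam and validation-based early stopping, early and late sensor
    fusion, subject-disjoint 9-fold cross-validation with balanced
    accuracy, exact Wilcoxon signed-rank comparisons and Cohen's kappa,
    and a seeded synthetic tri-modal movement simulator so the whole
    pipeline can be exercised without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
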