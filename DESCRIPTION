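Package: doserings
Title: Automatic Radiotherapy Planning with Dose Prediction and Dose-Ring
    Optimization Templates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for automatic volumetric modulated arc therapy (VMAT)
    and intensity-modulated radiotherapy (IMRT) planning built around
    three-dimensional dose prediction and the discretization of dose
    distributions into integer-gray isodose regions and dose rings.
    Provides a synthetic pelvic phantom generator (CT, target and
    organ-at-risk structures, reference dose), minimal DICOM-RT
    input/output (CT series, RTDOSE, RTSTRUCT), CT windowing and dose
    normalization, a residual 3D U-net dose-prediction model trainable on
    CPU, generation of treatment-planning-system constraint-function
    templates over dose rings, and plan evaluation via dose-volume
    histograms, conformity and homogeneity indices, dice similarity per
    isodose level, and gamma-index analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
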