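Package: libsseed
Title: Cultivar Discrimination from Laser-Induced Breakdown Spectra of Grape Seeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discriminating grape-seed cultivars from
    laser-induced breakdown spectroscopy (LIBS) emission spectra. Includes a
    synthetic-spectrum generator with an Echelle-like wavelength axis and
    configurable emission-line profiles, a preprocessing chain (range trimming,
    negative clipping, Daubechies wavelet denoising, min-max normalization),
    interval partial least squares (iPLS) spectral-region selection built on a
    NIPALS PLS1 core with cross-validated RMSECV, four supervised classifiers
    (RBF-kernel SVM, exact-design RBF network, extreme learning machine, and a
    one-dimensional convolutional neural network), and evaluation utilities
    with contingency-table classifier comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    kernlab,
    MASS,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
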