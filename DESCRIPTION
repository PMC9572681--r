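Package: oleaspec
Title: Visible/Near-Infrared Hyperspectral Chemometrics for Fruit
    Maturity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end chemometrics workflow for discriminating the
    ripeness stages of oilseed fruit from visible/near-infrared
    (400-1000 nm) hyperspectral images.  Provides reflectance
    calibration against white and dark reference frames, band-math
    segmentation and mean-spectrum extraction, spectral preprocessing
    (standard normal variate, max-min normalization, Savitzky-Golay
    derivatives), PLS-DA and PCA-DA classifiers with Venetian-blinds
    cross-validated dimension selection, wavelength selection by PCA
    loading peaks, synchronous two-dimensional correlation
    spectroscopy, and uninformative variable elimination chained with
    the successive projections algorithm (UVE+SPA), plus confusion
    matrix reporting with per-class sensitivity, specificity and
    precision.  A synthetic scene generator with known ground truth
    makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    png,
    signal,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
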