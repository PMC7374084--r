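Package: spechist
Title: Spectral Histopathology of FTIR Hyperspectral Tissue Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mid-infrared hyperspectral images of
    paraffin-embedded tissue sections. Provides digital de-paraffinization by
    extended multiplicative signal correction (EMSC) against a common target
    spectrum with a measured paraffin interference basis and polynomial
    baseline, Savitzky-Golay smoothing, fingerprint cropping, elimination of
    paraffin-dominated pixels, k-means segmentation of tissue images into
    histology-like clusters with centroid dendrograms, principal-component
    fed linear discriminant classification of normal versus cancer samples
    with ANOVA component selection under leave-one-sample-out
    cross-validation (ROC/AUC, sensitivity, specificity), and matching of
    discriminant loadings to glycan standard spectra. Includes a synthetic
    hyperspectral cohort generator so every stage is testable without
    instrument data, plus ENVI cube and CSV spectra-table input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    png,
    yaml,
    jsonlite,
    mclust,
    MASS,
    data.table,
    ape,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
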