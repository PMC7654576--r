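Package: retispec
Title: Bimodal Retinal Hyperspectral and OCT Analysis for Alzheimer's
    Disease Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for discriminating Alzheimer's disease
    patients from cognitively intact controls by combining snapshot
    mosaic hyperspectral retinal imaging with optical coherence
    tomography retinal nerve fiber layer (RNFL) thickness.  Provides a
    synthetic retinal phantom and cohort generator emulating a 4x4
    spectral-filter-on-CMOS snapshot sensor (16 bands, 460-620 nm),
    demosaicing and flat-field conversion to relative reflectance,
    retinal blood-vessel segmentation, anatomical region-of-interest
    placement relative to the optic-disc/fovea axis, spectral feature
    standardization, the cohort statistical battery (pooled t,
    Mann-Whitney, chi-square, covariate-adjusted regression, Bonferroni,
    SEM-overlap screening), and a from-scratch linear discriminant
    classifier evaluated by nested leave-one-out cross-validation with
    DeLong confidence intervals for the AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    png,
    EBImage,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
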