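Package: dcismorph
Title: Morphometric Profiling and Progression-Risk Modeling for Ductal
    Carcinoma In Situ
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A whole-slide morphometric analysis pipeline for ductal
    carcinoma in situ (DCIS) of the breast. Ingests segmented-object
    tables or label masks from H&E whole-slide images, applies rule-based
    quality-control filtering of nuclear and duct objects, computes 15
    per-duct morphological measurements, summarizes their distributions
    into 120 slide-level morphometric variables, prunes redundant
    variables by rank correlation, classifies risk of subsequent
    ipsilateral invasive breast cancer with a ridge-penalized logistic
    model under nested cross-validation, derives cluster-based
    morphometric signatures, and evaluates them with Kaplan-Meier and Cox
    proportional-hazards survival analysis. Includes segmentation
    validation metrics (intersection-over-union, duct-count correlation)
    and a synthetic slide and cohort generator so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    MASS,
    png,
    stats,
    survival,
    tiff,
    utils,
    yaml
Suggests:
    glmnet,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
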