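Package: digicomp
Title: Composite Digital Biomarkers of Disease Progression from
    Longitudinal Sensor Feature Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for constructing and evaluating composite digital
    biomarkers of disease progression from high-dimensional, longitudinal
    panels of wearable-sensor features. Provides a synthetic cohort
    generator emulating a four-group observational study design,
    epoch-to-task feature aggregation and quality control, linear
    mixed-effects univariate progression screening and association
    testing, generalized estimating equations (GEE) and SCAD-penalized
    GEE for longitudinal feature selection, subject-level cross-validated
    choice of the number of features, and a full evaluation battery for
    the resulting composite measure (progression p-values, effect sizes,
    coefficients of variation, and classification performance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    lme4,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
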