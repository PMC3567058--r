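Package: hemocc
Title: Nested Case-Control Analysis of Hemostatic Biomarkers with
    Measurement-Error Correction and Meta-Analytic Harmonization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical machinery for nested case-control studies of
    log-normally distributed circulating biomarkers (t-PA antigen, D-dimer,
    von Willebrand factor) and coronary heart disease. Provides per-1-SD
    standardized odds ratios from unconditional logistic regression with
    progressive covariate adjustment, quintile-group odds ratios with
    floated variances (floating absolute risk), regression-dilution-ratio
    estimation from serial measurements with correction of odds ratios to
    "usual" (long-term average) exposure levels, and harmonization of
    heterogeneous published risk estimates to a common per-1-SD scale with
    DerSimonian-Laird random-effects pooling, meta-regression, Egger
    small-study-bias diagnostics, and subgroup comparison. Includes a
    synthetic-cohort generator with known ground truth so every stage of
    the pipeline is testable without access to participant-level data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
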