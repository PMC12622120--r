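Package: aiescan
Title: Targeted Estimation and Testing of Average Interaction Effects
    Between DNA Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Semiparametric detection of epistasis between DNA variants
    (e.g. transcription-factor binding QTLs crossed with facilitator QTLs,
    optionally modified by sex) on binary or continuous traits. Implements
    model-independent average treatment effect (ATE) and 2-point / 3-point
    average interaction effect (AIE) estimands with confounder adjustment,
    targeted maximum likelihood estimation (TMLE) with cross-validated
    machine-learned nuisance functions, efficient-influence-curve standard
    errors and joint covariance, Hotelling's T-squared aggregation of
    allelic components, grouped Benjamini-Hochberg false discovery rate
    control, closed-form power analysis contrasting AIE with ATE
    detection, and a synthetic-cohort generator with Hardy-Weinberg
    genotypes, linkage disequilibrium and confounding for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    nnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
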