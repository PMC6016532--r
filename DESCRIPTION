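Package: gmerror
Title: Measurement-Error Analysis for 3D Landmark-Based Geometric Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying digitization and device error in repeated-
    measure 3D geometric morphometric designs. Implements generalized
    Procrustes superimposition with tangent-space projection, sliding of curve
    semilandmarks and surface patch points under the Procrustes-distance
    criterion, object-symmetry decomposition into symmetric and asymmetric
    shape components, Procrustes ANOVA with residual-randomization permutation
    tests, repeatability (intraclass-correlation analogue), per-group
    Procrustes variance with permutation comparison, and between-group PCA
    with leave-one-out cross-validated classification. Includes a synthetic
    landmark-data generator with known variance components for validating
    every stage of the pipeline, and readers/writers for common landmark file
    dialects (long/wide CSV and TPS).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
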