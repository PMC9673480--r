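Package: milkmediate
Title: Counterfactual Mediation Analysis for Mother-Milk-Infant Dyad Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for counterfactual-based mediation analysis of longitudinal
    mother-milk-infant dyad cohorts. Provides a seeded synthetic cohort
    generator with a known log-scale mediation structure, preprocessing of
    hormone assays (half-LOD substitution, adiposity indices and
    categorisation, milk energy from macronutrients, visit-centred age),
    24-hour test-weighing milk-intake estimation with quality control and
    hot-deck imputation, linear mixed-effect model fitting with per-subject
    random intercepts, and product-of-coefficients total/direct/indirect
    effect decomposition with Monte Carlo confidence intervals, including
    exposure-mediator interaction screening and exposure-level-specific
    decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
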