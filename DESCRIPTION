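Package: metgp
Title: Genomic Prediction for Single-Cross Hybrids in Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Two-stage genomic prediction for single-cross maize hybrids evaluated
    in multi-environment trials. Stage one fits per-trial fixed-effect models to
    plot data and returns adjusted hybrid means (eBLUEs) with an interquartile-range
    outlier filter. Stage two fits additive and additive-plus-dominance GBLUP models
    with compound-symmetric genetic correlations across environments by restricted
    maximum likelihood, using VanRaden additive and Vitezica dominance genomic
    relationship matrices built from parental SNP dosages and inferred hybrid
    genotypes. Tree-ensemble predictors (bagging, random forest, gradient boosting)
    with location and year factors, CV1/CV2 cross-validation with per-environment
    Pearson predictive ability, a phenotyping-budget calculator, and a synthetic
    testcross-trial simulator make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    rpart,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
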