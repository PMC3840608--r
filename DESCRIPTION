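Package: hdpsagg
Title: High-Dimensional Propensity Scores Under Hierarchical Code Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates how aggregating drug and diagnosis codes along
    hierarchical coding systems (ATC levels, ICD-9 digit truncation,
    multi-level CCS groupings) affects confounder selection and adjustment by
    the high-dimensional propensity score algorithm. Includes a synthetic
    claims-cohort generator with known true risk ratio and confounding by
    indication, the empirical covariate engine with Bross-formula
    prioritization, log-binomial risk-ratio models with propensity-score
    decile adjustment and a modified-Poisson fallback, resampling conditions
    for small cohorts, rare outcomes and low exposure prevalence, and
    residual-confounding metrics comparing aggregation scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    sandwich,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
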