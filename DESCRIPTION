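Package: mrmediate
Title: Two-Sample Mendelian Randomization Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) mediation
    analysis of an exposure-mediator-outcome triangle from GWAS summary
    statistics: instrument selection (p-value filtering, greedy LD clumping,
    proxy substitution, allele harmonization), univariable MR total effects
    (inverse-variance weighted, MR-Egger, weighted median) with the full set
    of sensitivity diagnostics, multivariable MR direct effects with
    conditional F-statistics, generalised Cochran's Q and Q-minimisation
    (Q-het) estimation with parametric bootstrap intervals, difference-method
    mediation with propagation-of-errors standard errors, a parallel
    observational two-regression mediation arm, and a synthetic-data
    generator with known causal structure so every estimator is testable by
    parameter recovery.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
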