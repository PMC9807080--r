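Package: rdhealth
Title: Relative Deprivation Indices and Moderated Mediation Models for
    Health Inequality in Clustered Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes individual relative income deprivation indices
    (Yitzhaki, Deaton, Podder, within-group percentile rank) inside
    reference groups such as villages, fits two-level random-intercept
    health-outcome models, runs stepwise mediation through psychological
    capital with bootstrap confidence intervals for indirect effects, and
    tests moderation of deprivation effects by absolute family income with
    centered interaction terms. Ships a village-clustered synthetic survey
    generator with known structural parameters so every stage has a
    parameter-recovery test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
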