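Package: twinliab
Title: Liability-Threshold Twin Models for Binary Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the classical twin design applied to dichotomous
    traits: simulation of twin cohorts under the liability-threshold model,
    questionnaire-based phenotype coding with exclusion rules, descriptive
    epidemiology (prevalence, sex-difference tests, odds ratios), and
    maximum-likelihood estimation of tetrachoric correlations and
    ACE/AE/CE/E variance components from zygosity-group concordance tables,
    with likelihood-ratio model comparison and profile-likelihood
    confidence intervals. Developed around the structure of large
    population-based twin registries screening for parent-reported speech
    and language difficulties.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mvtnorm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
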