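Package: twinliab
Title: Liability-Threshold Heritability Analysis of Censored Binary Traits in Twin Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classical twin-design analysis of a rare, late-onset
    binary trait observed through registry linkage with right censoring and
    competing mortality, motivated by total hip arthroplasty for primary hip
    osteoarthritis. Provides a synthetic twin-register generator with
    correlated liabilities and age-dependent onset; registry file linkage and
    cohort assembly; pairwise, proband-wise and case-wise concordance;
    maximum-likelihood tetrachoric correlations; saturated and ACE/ADE/AE/CE
    liability-threshold model fits by weighted bivariate probit likelihood
    with inverse-probability-of-censoring weights; Aalen-Johansen cumulative
    incidence under competing risks; and age-resolved concordance and
    heritability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    mvtnorm,
    data.table,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
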