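Package: pretermburden
Title: Markov Cohort Modelling of the Economic Burden of Preterm Birth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A gestational-age-stratified Markov cohort model of the
    ten-year economic burden of preterm birth. Provides a deterministic
    cohort engine for survival and disability trajectories, a multi-layer
    costing engine with annual discounting and national scaling, a
    claims-style resource-utilization estimator with cohort exclusion
    rules, a synthetic generator for linked physician-billing and
    hospital-discharge tables, and probabilistic sensitivity analysis
    over parameter uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
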