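Package: efrinit
Title: Shared-Responsibility Initiation Rates and the Injector Replacement Rate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the initiation of novices into injection drug
    use from cross-sectional injector surveys. Implements the
    equivalent-of-full-responsibility (EFR) per-annum initiation-rate statistic
    with paired nonparametric bootstrap confidence intervals, precision-weighted
    log-rate regression across survey subgroups, a piecewise-constant discrete
    hazard model of time to first incarceration fitted by maximum likelihood
    with profile-likelihood intervals, and a discrete-time injector
    replacement-rate model combining EFR rates, incarceration history and
    geometric career cessation, including the closed-form immediate quit rate
    that holds the injector population stable. A seeded synthetic-cohort
    generator emulating the record structure of Scotland's Needle Exchange
    Surveillance Initiative (NESI) 2008-2009 survey makes every stage testable
    without access to restricted microdata.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
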