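Package: currentsurv
Title: Current Cumulative Incidence and Current Leukaemia-Free Survival for
    Remission-Relapse Event Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nonparametric estimation of the probability of being alive and
    in disease remission over time for patients who can achieve and lose
    remission repeatedly, as in chronic myeloid leukaemia treated with
    tyrosine kinase inhibitors. Implements the current cumulative incidence
    of leukaemia-free patients (a linear combination of Aalen-Johansen
    cumulative incidence estimates) and the current leukaemia-free survival
    (a linear combination of Kaplan-Meier estimates on a clock reset at the
    first remission), together with a progressive multi-state Markov
    comparator, Efron bootstrap percentile confidence intervals, and a
    semi-Markov Weibull cohort simulator with median-absolute-deviation and
    confidence-interval-coverage evaluation harnesses.
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
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
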