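Package: prepdyn
Title: Trial-Resolved Analysis of Temporal Preparation Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing variable-foreperiod experiments in which a
    warning stimulus category is probabilistically associated with foreperiod
    duration. Provides a synthetic trial generator that reproduces a two-phase
    (Acquisition/Transfer) design with exponential and anti-exponential
    foreperiod distributions and a time-varying generative inverse-RT model;
    trial- and participant-level exclusion rules; linear mixed-model comparison
    on inverse reaction time with BIC-based Bayes factors; rolling-window
    regression coefficient time courses; cluster-based permutation inference
    with a participant sign-flip null; simulation-based power estimation for
    the mixed-model contrasts; and within-subject (Cousineau-Morey) confidence
    intervals with figure helpers.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    readr,
    rlang,
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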