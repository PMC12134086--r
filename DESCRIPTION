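Package: crabfate
Title: Fate-Tracking Analysis of Coral-Dwelling Gall Crab Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse longitudinal fate-tracking surveys of
    coral-dwelling gall crabs (Cryptochiridae): classification of
    colonization, extinction and host-mortality-driven extinction events
    from dwelling observations; per-colony turnover and mortality rates;
    zero-one-inflated beta (BEINF) regression of turnover on site and
    time-point covariates; permutation tests for mortality trends around a
    bleaching disturbance; Degree Heating Weeks thermal-stress computation
    from logger temperature series; and baseline community statistics
    (Hellinger PCA, nested PERMANOVA, SIMPER, Hill diversity). A synthetic
    survey generator emulating the study design makes the whole pipeline
    testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    fitdistrplus,
    withr
Config/testthat/edition: 3
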