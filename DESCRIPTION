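Package: relianceSDT
Title: Hierarchical Bayesian Signal Detection Analysis of Reliance on
    Fallible AI Advice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies appropriate reliance on fallible AI advice in
    two-session classification experiments. Provides a synthetic-cohort
    generator emulating a phase-structured Wizard-of-Oz advice schedule,
    a hierarchical Bayesian equal-variance Signal Detection Theory model
    (participant- and group-level d-prime and criterion with log-linear
    correction, fitted by MCMC through JAGS), posterior d-prime
    differences between advised and unadvised sessions split by advice
    correctness, behavioral reliance metrics (acceptance rate, switch
    percentage, contingency tables), and a Bayesian linear mixed
    regression of repeated trust and distrust self-reports under planned
    contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    MASS,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
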