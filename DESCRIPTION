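Package: memfid
Title: Mixture Modeling and Signal Detection Analysis of Object-Location Memory Fidelity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing continuous-report object-location memory
    experiments across the lifespan. Fits von Mises-uniform mixture models
    (standard and swap/misbinding variants) to circular localization errors by
    maximum likelihood and by Bayesian MCMC, separating retrieval success (pT)
    from memory precision (kappa), with model selection, posterior-overlap group
    comparison, fit-quality flags and a guess-cutoff adjusted precision metric.
    Converts accuracy to d-prime for m-alternative forced-choice mnemonic
    discrimination and 3-stimulus oddity perceptual discrimination under the
    differencing model. Includes a seeded synthetic-task generator emulating a
    3-object display design, a subject-level analysis pipeline with exclusion
    rules and composite scores, and bootstrap, dependent-correlation and
    within-display dependency statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
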