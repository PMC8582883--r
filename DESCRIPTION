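Package: hmvlogit
Title: Mixed Logit Injury-Severity Models with Heterogeneity in Means and
    Variances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation and post-estimation tooling for four-category crash
    injury-severity models based on the random-parameters (mixed) multinomial
    logit, where the mean and the variance of each random coefficient may
    themselves depend on crash covariates. Models are estimated by maximum
    simulated likelihood over inverse-normal-transformed Halton draws, with
    analytic gradients, numerical-Hessian standard errors, a nested model
    ladder, likelihood-ratio model-separation and parameter-transferability
    tests, average discrete-change marginal effects, and random-parameter
    distribution summaries. A seeded synthetic crash-data generator with
    ground-truth manifests allows the full pipeline to run without external
    data.
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
    utils,
    withr,
    yaml
Suggests:
    nnet,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
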