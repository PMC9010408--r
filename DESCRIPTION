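Package: affectug
Title: Affect-Modulated Inequality Aversion in the Iterative Ultimatum Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of an iterative Ultimatum
    Game in which a proposer's offers and facial-emotion displays evolve by
    response-conditioned sliding-window sampling. Provides the closed-loop
    task engine, nonlinear (Prelec-type) weighting of perceived facial
    affect, a registry of eleven candidate decision-value models including
    emotion-modulated inequality aversion, exhaustive grid-based Bayesian
    parameter estimation with BIC and random-effects model selection,
    model-free behavioural statistics (acceptance grids, lagged logistic
    regressions, variance inflation factors), a recursive Bayesian filter
    yielding trial-wise surprise, volatility and noise regressors, and a
    time-resolved pupillometry regression pipeline. A synthetic-data module
    generates complete cohorts with known ground truth so that every stage
    of the pipeline can be validated by parameter- and model-recovery
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
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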