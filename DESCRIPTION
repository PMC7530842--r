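Package: mestrack
Title: Motor Error Scores from Continuous Tablet Tracking Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies upper-extremity motor dysfunction from a continuous
    target-tracking task. Generates stochastic constant-speed cubic Bezier
    target paths, simulates control-, Parkinson- and essential-tremor-like
    cursor and stylus-force traces, computes eight kinematic and force
    metrics over 1-second epochs (including an analytic-signal tremor
    envelope and an exponential slowness transform), and scores each epoch
    with a signed distance to a Monte-Carlo-averaged linear support vector
    machine hyperplane (the Motor Error Score, MES). Includes downstream
    evaluation tools: percentile-wise correlation of MES with clinical
    ratings, pairwise and pooled ROC/AUC, metric-weight profiles,
    label-shuffling and metric-exclusion controls, within-subject two-state
    classification, and a tremor-dominant phenotype ratio rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    signal,
    e1071,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
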