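Package: ssgvalidity
Title: Representativeness and Predictive Validity of Small-Sided Soccer Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies individual in-game soccer performance from
    event-coded match logs and assesses how well 7-vs-7 small-sided games
    (SSGs) represent and predict 11-vs-11 game performance. Count-type
    performance indicators are converted to rates per six-minute bout;
    indicators with a success/failure outcome are scored with
    random-intercept multilevel logistic regression (empirical-Bayes
    posterior scores); indicator weights are derived from team-wise Spearman
    correlations with a shots-on-target success proxy aggregated by
    DerSimonian-Laird random-effects meta-analysis; composite offensive and
    defensive scores combine the weighted within-team z-scores. Format
    representativeness is tested with a multinomial goodness-of-fit test
    with adjusted standardized residuals and a rank correlation between
    event-frequency distributions. A seedful synthetic-study generator with
    known ground truth supports calibration and parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    metafor,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
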