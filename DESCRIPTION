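Package: leadsim
Title: Emergent Leadership in Collective Movement Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An event-driven, continuous-time simulator of collective movement
    initiation in animal groups, in which initially identical individuals
    differentiate into stable leaders and followers through experience. Each
    individual carries a leadership tendency that modulates its initiation,
    following, and cancellation rates through a sigmoid 'k factor' and is
    reinforced after every initiation attempt by a bounded linear learning
    rule. The package provides the rate model, the stochastic attempt engine,
    evaluation and treatment-grid runners with matched seeding, least-squares
    changepoint segmentation of leadership-tendency time series with BIC model
    selection, and replicate-level reporting of success and differentiation
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
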