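Package: gspois
Title: Group Sequential Design of Two-Arm Trials with Poisson Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design and evaluation of group sequential two-arm experiments
    with Poisson distributed outcomes. Provides exact operating
    characteristics based on the Skellam distribution of the per-stage
    difference in event totals, asymptotic operating characteristics via the
    canonical joint normal distribution of Wald statistics, error-spending
    derivation of stopping boundaries, group-size determination, near-optimal
    spending-grid searches and an exhaustive optimal search for two-stage
    exact designs, together with Monte Carlo validation of any design.
    Maximal type-I and type-II error rates are controlled over composite
    (interval) hypotheses on the event rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
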