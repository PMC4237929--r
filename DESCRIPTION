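Package: asavtriage
Title: Mass-Casualty Primary Triage Algorithms: Simulation and Diagnostic Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for studying primary mass-casualty triage algorithms of the
    START family, centred on the Amberg-Schwandorf algorithm (ASAV) in which
    non-physician providers may assign the dead (black) category only on definite
    signs of death. Provides a data-driven decision-tree engine loadable from
    JSON, a synthetic generator for casualty description cards, provider teams
    and simulated triage runs, diagnostic test-performance evaluation
    (sensitivity, specificity, likelihood ratios, over- and under-triage with
    Wald confidence intervals), triage-time summaries with ANOVA and Bonferroni
    post-hoc comparisons, and casualty-mix-weighted incident-planning
    calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
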