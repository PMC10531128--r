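Package: seqcua
Title: Markov Cohort Cost-Utility Analysis of Sequential Treatment Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort state-transition (Markov) modelling for cost-utility
    analysis of ordered, no-backtracking treatment sequences, built around
    the sequential pharmacological-to-surgical pathway used in knee
    osteoarthritis. Provides forward cohort simulation with an absorbing
    terminal state, discounted cost and QALY accumulation with optional
    half-cycle correction, incremental cost-effectiveness ratios with
    dominance handling, GDP-per-capita willingness-to-pay classification,
    one-way (tornado) deterministic sensitivity analysis, a synthetic
    scenario generator for property testing, and a bundled fixture of six
    published Vietnamese treatment regimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
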