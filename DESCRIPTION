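Package: markovcea
Title: Markov Cohort Cost-Effectiveness Analysis of First-Line
    Immunotherapy in Advanced NSCLC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-state (progression-free, progressed, dead) Markov
    cohort model for cost-effectiveness analysis of nivolumab plus
    ipilimumab versus platinum-doublet chemotherapy as first-line
    therapy in advanced non-small-cell lung cancer, stratified by
    PD-L1 expression. Provides Weibull survival extrapolation and
    fitting to digitized Kaplan-Meier coordinates, cohort simulation
    over a 20-year horizon with 6-week cycles, discounted cost and
    QALY accrual, incremental cost-effectiveness ratios, one-way
    (tornado) and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, threshold-price solving,
    and a synthetic Kaplan-Meier data generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
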