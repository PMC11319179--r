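Package: screencea
Title: Cost-Effectiveness Analysis of Type 2 Diabetes Screening Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree plus Markov cohort modelling of type 2 diabetes
    screening programmes (point-of-care HbA1c, venous HbA1c and fasting
    capillary glucose) in urban and rural settings. A one-shot screening
    decision tree splits the population into diagnosed, missed, misdiagnosed
    and true-negative arms; arms progress through annual-cycle disease
    models with hazard-ratio adjustment for missed diagnosis and rural
    residence, accruing discounted costs and quality-adjusted life years
    with half-cycle correction. Provides incremental cost-utility ratios
    with dominance handling, one-way (tornado) and probabilistic sensitivity
    analysis with beta/lognormal/uniform parameter distributions,
    cost-effectiveness acceptability curves, a seeded individual-level
    microsimulation mode, and a synthetic parameter generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
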