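Package: ktcua
Title: Cost-Utility Analysis of Preemptive and Non-Preemptive Kidney
    Transplantation Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree plus five-state Markov cohort model for lifetime
    cost-utility analysis of kidney replacement strategies in end-stage kidney
    disease: preemptive living-related kidney transplantation (KT),
    non-preemptive living-related KT, and non-preemptive deceased-donor KT.
    Implements life-table mortality adjusted by age-banded standardized
    mortality ratios, discounted cost/life-year/QALY accumulation, ICER and
    dominance-frontier comparison, one-way deterministic sensitivity analysis
    (tornado), probabilistic sensitivity analysis with moment-matched beta and
    gamma distributions, cost-effectiveness plane and acceptability curves, and
    a synthetic patient-level cohort generator with parameter re-estimation for
    end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
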