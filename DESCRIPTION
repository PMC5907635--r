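Package: oabcea
Title: Markov Cost-Utility Model of Oral Antimuscarinic Treatment for
    Overactive Bladder
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Cohort state-transition (Markov) model for the cost-utility
    analysis of oral antimuscarinic agents in overactive bladder from a UK
    NHS perspective. Simulates symptom-severity dynamics (micturition
    frequency and incontinence, five levels each), a treatment pathway with
    discontinuation, switching, restart and botulinum toxin type A, and
    adverse events, over a five-year horizon with monthly cycles and 3.5%
    annual discounting. Includes a synthetic trial-data generator,
    multinomial transition and EQ-5D utility regressions, calibration of
    comparator transition matrices to network-meta-analysis effects,
    discounted cost and QALY accumulation with ICER and dominance
    classification, and deterministic and probabilistic sensitivity
    analyses with cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nnet,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
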