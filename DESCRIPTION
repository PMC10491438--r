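Package: dtascea
Title: Cost-Effectiveness Modelling of Direct-to-Angiography-Suite Stroke Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness pipeline comparing direct
    transfer to the angiography suite (DTAS) with initial transfer to the
    emergency room (ITER) for patients with suspected large-vessel-occlusion
    stroke. Couples a one-year decision tree over 90-day modified Rankin Scale
    outcomes to a nine-year five-state Markov cohort model with age- and
    disability-dependent mortality, and computes discounted costs, QALYs,
    ICERs and net monetary benefit. Includes scenario analyses, one-way
    (tornado) sensitivity analysis, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, a synthetic parameter-set
    generator, and an independent patient-level microsimulation used to
    validate the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
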