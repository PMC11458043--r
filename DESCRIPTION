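Package: ppicea
Title: Cost-Effectiveness Analysis of Pharmacist-Led Proton Pump
    Inhibitor Deprescribing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model of a pharmacist-led
    proton pump inhibitor (PPI) deprescribing service versus usual care in
    older adults, from a public healthcare provider perspective. Builds a
    one-year decision tree over inappropriate-use triage, deprescribing
    recommendations (discontinuation, dose reduction, switch to a histamine-2
    receptor antagonist), prescriber acceptance, symptomatic rebound with
    reinstatement, and PPI-associated adverse events (hypomagnesemia,
    pneumonia, Clostridium difficile infection) with hospitalization and
    mortality branches. Computes expected direct medical cost and
    quality-adjusted life-year (QALY) loss per strategy, incremental
    cost-effectiveness ratios with dominance classification and net monetary
    benefit, one-way (tornado) sensitivity analysis with threshold detection,
    and probabilistic sensitivity analysis via Monte Carlo sampling of
    beta, gamma, and triangular parameter distributions, with
    cost-effectiveness acceptability curves. The bundled configuration is a
    published Hong Kong parameter set; all inputs are config-driven so the
    model can be re-run with region-specific values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
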