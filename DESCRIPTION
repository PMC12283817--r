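Package: adcase
Title: Decision-Analytic Cost-Effectiveness Modelling of Antenatal
    Depression Case Finding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree cost-effectiveness model comparing no, universal,
    and targeted case finding for antenatal depression over a 20-week
    antenatal horizon from the perspective of the English NHS. Includes a
    synthetic individual-level cohort generator with correlated risk factors
    and latent-trait screening-instrument responses, derivation of model
    parameters (stratified prevalence, instrument operating characteristics,
    utilities) from cohort data, deterministic evaluation of the decision
    tree with trajectory-based QALY accrual, probabilistic sensitivity
    analysis with beta-distributed probabilities and utilities, incremental
    cost-effectiveness analysis with dominance and cost-effectiveness
    acceptability curves, projection onto an annual birth cohort, and a
    declarative one-way sensitivity-scenario engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
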