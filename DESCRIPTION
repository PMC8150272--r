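Package: ventinvert
Title: Inverse Estimation of Mechanical Ventilator Settings via Surrogate
    Networks and a Graded Particle Swarm Optimizer
Version: 0.1.0
Authors@R:
    person("ventinvert", "maintainers", email = "ventinvert@example.org",
           role = c("aut", "cre"))
Description: Estimates mechanical ventilator settings that reproduce a
    desired set of patient observations.  A feed-forward neural surrogate is
    trained on cohort records mapping eight ventilator/demographic inputs
    (SetP, PIP, PEEP, PSV, RR, FiO2, age, weight) to seven patient responses
    (Vti, Cdyn, EtCO2, SpO2, HR, BP, temperature), and the surrogate is then
    inverted with a Graded Particle Swarm Optimizer (GPSO): a grouped swarm
    with per-group leaders and a universal leader that adds a third
    attraction term to the classic particle velocity update.  The package
    also provides the supporting data pipeline (neural-network imputation of
    missing clinical fields with truncation to observed bounds, cohort
    segregation) and a synthetic ventilated-patient generator with a known
    ground truth so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
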