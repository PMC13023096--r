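Package: boostcea
Title: Markov Cohort Cost-Effectiveness Model of Stem-Cell Reserve
    Collection for CAR T-Cell Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic Markov cohort model comparing universal
    proactive autologous stem-cell reserve collection ("boost") against no
    reserve for patients receiving CAR T-cell therapy for multiple myeloma.
    Implements a seven-state monthly-cycle state-transition model with
    cause-split absorbing death states, deterministic cohort propagation
    with expected-event accounting, a seeded individual-level
    microsimulation, constant-hazard survival-to-probability conversion and
    bisection calibration of relapse mortality, cost accumulation and
    incremental-cost analysis, one-way deterministic sensitivity analysis
    (tornado), probabilistic stress testing over uniform parameter ranges,
    and an ordinary-least-squares key-driver analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
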