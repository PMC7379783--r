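Package: calfcontrib
Title: Calf Muscle Force Estimation and Phase-Wise Contribution Analysis for Running
Version: 0.1.0
Authors@R:
    person("calfcontrib", "developers", email = "calfcontrib@example.org",
           role = c("aut", "cre"))
Description: Estimates individual calf muscle forces during a running stride from
    motion-capture marker trajectories and force-plate records, using Newton-Euler
    inverse dynamics about a reduced ankle/subtalar/metatarsophalangeal model and
    frame-wise static optimization that minimizes the sum of squared muscle
    activations under moment-balance and force-bound constraints. Computes
    gait-phase-wise individual muscle contribution percentages, compares shoe-weight
    conditions with one-way repeated-measures ANOVA and Fisher LSD post hoc tests,
    and ships a seeded synthetic running-trial generator with known ground-truth
    muscle forces for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
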