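Package: statordyn
Title: Multi-State Stator Remodeling Kinetics of the Bacterial Flagellar Motor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mechano-adaptive stator remodeling in the
    bacterial flagellar motor. Implements a four-state (diffusive, loosely
    bound, tightly bound, hidden) stochastic kinetic model of stator-unit
    turnover with closed-form first-passage-time dwell statistics, an exact
    event-driven (Gillespie) simulator that generates synthetic rotation-speed
    traces, a change-point step-fitting algorithm for noisy single-motor speed
    records, dwell-time and hidden-state statistics, and inference of the
    kinetic rate constants from dwell statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
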