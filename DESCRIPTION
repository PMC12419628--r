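Package: lhnsim
Title: Agent-Based Simulation of Collaborative Learning Health Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete-time agent-based model of a Learning Health Network
    (LHN): patients and clinicians coproduce knowledge through clinical
    encounters, engagement spreads over influence networks, and a shared
    knowledge commons with exponential decay feeds treatment decision
    making (praxis, selection efficiency, evaluation accuracy). Includes
    care-center level interventions (pre-visit planning and an enhanced
    registry), seeded reproducible simulation runs, and experiment
    harnesses: Latin hypercube sensitivity analysis with partial rank
    correlation coefficients and bootstrap confidence intervals, contour
    grid exploration of the solution space, and a 3x3x3 factorial
    intervention experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
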