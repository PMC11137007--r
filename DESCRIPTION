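Package: isosched
Title: Optimal Seasonal Scheduling of Isoprene Production in Leaves
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Solves the seasonal optimal-control problem for the production of
    a highly volatile, leaf-protecting biogenic volatile organic compound
    (isoprene) by a deciduous tree. Leaf area decays under background loss and
    a heat-stress hazard that isoprene suppresses; the tree maximises total
    net photosynthesis over the season. The package implements the Pontryagin
    maximum-principle solution (backward costate integration with the
    feedback-substituted optimal control, forward state integration),
    closed-form and general switching-time computations, phase
    classification, peak-shift and elasticity diagnostics, a brute-force
    direct-optimization oracle for validating optimality, scenario
    configurations for the canonical seasonal cases, and a small command-line
    interface.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
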