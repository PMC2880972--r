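Package: crowdfba
Title: Reduced Flux-Balance Model of ATP Production Under Molecular Crowding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-pathway flux-balance model of cellular ATP production in
    which glucose uptake is partitioned between aerobic glycolysis (lactate
    excretion, 2 ATP per glucose) and oxidative phosphorylation (38 ATP per
    glucose), constrained by the glucose uptake capacity and by the solvent
    capacity of the cytoplasm (molecular crowding). Provides the analytic
    piecewise-optimal flux solution and an independent linear-programming
    oracle, the estimation chain from enzyme kinetics and specific volumes
    to crowding coefficients and the predicted switch threshold, unit
    conversions between common flux-reporting bases, hinge (x-intercept)
    regression to estimate the empirical lactate-overflow threshold from
    flux data, and a synthetic flux-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
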