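Package: oxeit
Title: Simulated Bioimpedance Monitoring of ECMO Oxygenators for Thrombus
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Finite element simulation of multi-electrode bioimpedance
    measurements inside an extracorporeal membrane oxygenation (ECMO)
    oxygenator. Provides a parametric oxygenator geometry with a mid-height
    separation grid, a deterministic tetrahedral mesher, a complete electrode
    model forward solver with adjoint Jacobian sensitivity analysis,
    sensitivity-based selection of four-point injection-measurement patterns
    (greedy Gram-determinant maximization plus L1/L2 ranking), a
    flow-informed spherical thrombus placement sampler, a neural surrogate
    for electrode array design, and a neural classifier that flags
    thrombus-induced conductivity anomalies from relative voltage changes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
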