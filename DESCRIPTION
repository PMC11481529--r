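Package: mpetcsf
Title: Multi-Network Porous-Medium Modelling of Brain CSF Circulation and Infusion Tests
Version: 0.1.0
Authors@R:
    person("MPET", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Simulates cerebrospinal and interstitial fluid circulation in the brain
    parenchyma as a seven-compartment porous-medium (simplified MPET) system of
    arterial, capillary and venous blood, their perivascular spaces, and the
    extracellular space. The parabolic pressure equations are discretized with linear
    tetrahedral finite elements and backward Euler in time, and coupled to a lumped
    nonlinear-compliance model of subarachnoid CSF pressure to simulate constant-rate
    infusion tests. Includes a synthetic brain-like mesh generator matched to
    cohort-average morphometrics, outflow-resistance calibration, parameter-variation
    scenarios, and post-processing of pressures, superficial velocities, Peclet
    numbers and intercompartmental flows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
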