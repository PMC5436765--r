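Package: hpaxis
Title: Stoichiometric Network Model of Rat HPA Axis Dynamics Under
    Lateral Hypothalamic Kindling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action simulation and analysis of a 25-reaction, 11-species
    stoichiometric network model of the rat hypothalamic-pituitary-adrenal
    (HPA) axis. Provides the reaction network with published rate constants,
    an asymmetric 24-hour circadian forcing of corticotrophin releasing
    hormone (CRH) production, stiff ODE integration of control, sham and
    lateral-hypothalamic-kindling (LHK) scenarios with stop-and-restart
    additive CRH pulse perturbations, ultradian and circadian oscillation
    analytics for corticosterone time courses, a synthetic blood-sampling and
    ELISA measurement-noise generator, and least-squares calibration of the
    pulse intensity and stress multiplier from sampled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
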