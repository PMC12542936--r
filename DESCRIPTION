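Package: nanotwin
Title: Desk-Scale Digital Twin of a Dielectrophoretic Sensing Nanoprobe
Version: 0.1.0
Authors@R: person("Nanotwin", "Developers", role = c("aut", "cre"),
    email = "maintainers@nanotwin.dev")
Description: Simulation toolkit for a label-free robotic nanoprobe that
    senses reactive oxygen and nitrogen species (ROS/RNS) amperometrically
    and extracts mitochondria by dielectrophoresis (DEP).  Implements
    frequency-dependent Clausius-Mossotti polarizability (including the
    single-shell organelle model), a calibrated analytic tip-field model
    with force, potential and trapping-radius computations, overdamped
    Brownian-dynamics trapping/release/translation simulations, an
    amperometric sensor model with sealed-chamber depletion kinetics and
    nonlinear decay fitting, spike/threshold detectors, a vision pipeline
    (tip localization by background subtraction, classical cell detection,
    motion-history-image contact detection), an automated
    sense-then-extract protocol controller with full event logging, and
    seeded synthetic-world generators for every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
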