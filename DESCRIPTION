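Package: dynaselect
Title: Dynamics-Aware Prediction of Chemo- and Stereoselectivity from
    Stationary-Point Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts product distributions of organic reactions whose
    selectivity is controlled by reaction dynamics rather than transition-state
    theory alone. From quantum-chemistry stationary points (geometries, Gibbs
    free energies, harmonic normal modes) it combines Boltzmann populations of
    competing first transition states with a trajectory-stream analysis on a
    two-dimensional bond-difference projection of the potential energy surface,
    including a multi-product extension for bifurcations feeding more than two
    channels. Ships an analytic bifurcating model-surface generator with a
    quasi-classical trajectory oracle used to validate the stream-partition
    core.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
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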