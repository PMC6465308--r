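Package: transpath
Title: Transition-Path Shooting Analysis for Elevator-Type Transporter Dynamics
Version: 0.1.0
Authors@R:
    person("Path", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for two-segment transition-path shooting and its analysis
    layers: a Langevin toy dynamics engine on analytic potentials,
    Maxwell-Boltzmann velocity draws, sign-inverted conjugate shooting with
    stitching of committed segments into continuous transition paths,
    committor estimation, and maximum-likelihood optimization of a linear
    reaction coordinate under a tanh committor model.  Structural order
    parameters for elevator-type membrane transporters are included:
    least-squares rigid-body superposition, rotation angle and axis
    extraction, domain translation/rotation relative to inward- and
    outward-open references, a continuous hydration order parameter, and
    discrete water-access-state classification by single-linkage water
    clustering.  Synthetic fixture generators provide protein-like frames
    with known ground truth so the whole pipeline is testable without
    molecular dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    igraph
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
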