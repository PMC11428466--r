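Package: righting
Title: Biomechanics of Terrestrial Self-Righting from 3D Landmark Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for terrestrial self-righting by insects,
    built around high-speed multi-camera 3D landmark tracking and a rendered
    3D body model. Computes rigid-body attitude (quaternions, Tait-Bryan
    Euler angles, the vertical component of the dorsoventral axis), angular
    velocity, mesh-based mass properties, an articulated body-plus-leg
    ("anchor") inertia assembly, inverted-physical-pendulum template
    quantities (orbital kinematics, available kinetic energy, natural
    period, reaction torque and force per leg), gravitational potential
    energy and the righting number, support-polygon static stability
    margins, pitch-roll potential energy landscapes, normalized
    cross-correlation of leg motions, and behavioral (ethogram) summaries.
    Includes a deterministic synthetic-trial generator (a pivoted rigid body
    with kinematically prescribed legs) so every stage of the pipeline is
    testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
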