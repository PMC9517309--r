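Package: sitstand
Title: Sit-to-Stand Skeletal Kinematics and Ergonomic Seat Design for Elderly Users
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sit-to-stand transitions captured as 3D
    skeletal key-points. Converts 25 tracked joints to 12 named joint angles,
    clusters per-frame postures into transition stages, extracts per-angle
    activity thresholds for elderly and young-control cohorts, ranks angle
    importance with a small neural network and permutation importance,
    computes analytic-hierarchy-process (AHP) criterion weights with
    consistency checks, and maps anthropometry plus angle thresholds to seat
    design parameters through a comfort model. Includes a seeded synthetic
    motion generator (planar kinematic chain with keyframe interpolation) so
    that every stage is testable without motion-capture recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
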