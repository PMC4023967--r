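Package: gaitbalance
Title: Mapping Clinical Evaluations to Gait Balance Control with
    Levenberg-Marquardt Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying whole-body balance control during gait in
    elderly adults.  Computes the three standard center-of-mass (CoM) /
    base-of-support (BoS) interaction measures from gait trajectories
    (CoM-BoS distance, CoM displacement along the velocity vector to the
    BoS boundary, and BoS area at heel strike), fits three-layer
    feed-forward regression networks trained with the Levenberg-Marquardt
    algorithm to map clinical evaluations onto those measures, and runs the
    full cross-validated grid experiment over input groupings, hidden-layer
    sizes and error goals.  A seeded synthetic-cohort generator reproduces
    the marginal structure of a 56-subject elderly cohort together with
    trajectory-level gait trials, so the complete analysis can be exercised
    end to end without motion-capture data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
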