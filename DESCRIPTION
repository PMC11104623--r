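Package: gazedecode
Title: Simulation and Analysis of Gaze-Based Target Decoding with
    Distorted Saccade-Endpoint Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying oculomotor learning in a simulated
    gaze-controlled human-machine interface. An eight-object circular
    scene decodes the intended target from the (systematically rotated)
    primary saccade endpoint and returns either motor feedback (a dot at
    the distorted endpoint) or action feedback (the decoded object
    highlighted). The package provides online and offline saccade event
    detection at 1000 Hz with velocity criteria, per-trial oculomotor
    metrics (signed endpoint angles, area-based trajectory curvature,
    learning-phase assignment), permutation statistics (t-tests, a mixed
    ANOVA, a participant-level learning-trend test), Hartigan's dip
    statistic with Monte-Carlo p-values, and a synthetic-data generator
    with minimum-jerk kinematics, error-based and reward-based learners,
    corrective saccades, and cross-session savings, so that the full
    pipeline can be exercised and calibrated without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
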