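Package: chewgear
Title: Jaw Kinematics and Muscle Architecture Dynamics from Marker-Based
    Videoradiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for marker-based (XROMM-style) analysis of jaw kinematics
    and dynamic muscle architecture during chewing. Reads XMALab-style 3D
    marker trajectories, applies zero-phase Butterworth filtering, fixes a
    cranial reference frame and computes per-frame mandibular rigid-body
    transforms by singular value decomposition, segments gape cycles and
    detects the four gape-cycle phases from jaw acceleration, computes
    fascicle and whole-muscle lengths, planar fascicle angles, instantaneous
    velocities, LOESS-smoothed velocity curves and the architectural gear
    ratio (AGR), and fits the accompanying nested mixed-model statistics
    (marginal and conditional R-squared, reduced major axis regression,
    sequential Bonferroni adjustment). A synthetic jaw and pinnate-muscle
    generator with closed-form ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    yaml,
    lme4,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
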