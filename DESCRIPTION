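Package: reachkin
Title: Movement Quality and Cognitive Load Analysis for 3D Reaching Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for analysing 3D goal-directed reaching
    movements recorded under different visualization technologies (immersive
    virtual reality, augmented reality, 2D screen). Provides the experimental
    protocol geometry (workspace, target locations, collider shapes, block
    structure), a seeded synthetic-data generator built on minimum-jerk
    kinematics, trial segmentation, movement-quality metrics (normalized
    duration, straightness ratio, peak velocity, velocity-peak count, movement
    onset), extreme-outlier removal, dual-task counting and questionnaire
    (SUS, IMI, NASA-RTLX) scoring, and a repeated-measures statistical harness
    (two-way RM-ANOVA with Greenhouse-Geisser correction, RM-MANOVA with Wilks'
    lambda, Friedman test with Kendall's W, Bonferroni-corrected post-hoc
    paired t-tests with Cohen's d).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
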