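Package: kinadapt
Title: Closed-Loop Difficulty Regulation and Movement Kinematics for
    Immersive VR Motor Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for self-adaptive serious-game
    motor-learning studies in immersive virtual reality. Implements a
    closed-loop difficulty regulator driven by block-level success-rate
    bands and error diagnostics, a kinematic metric engine for 3D
    controller trajectories (zero-phase Butterworth filtering,
    speed-accuracy trade-off, spectral arc length smoothness), synthetic
    generators for learner agents, minimum-jerk drawing trajectories with
    submovements, and pre/post/follow-up outcome cohorts, and the
    repeated-measures statistical pipeline (Shapiro-Wilk gating, one-way
    repeated-measures ANOVA or Friedman omnibus, Bonferroni or
    Tukey-adjusted pairwise post hocs, eta-squared, epsilon-squared,
    Cohen d and Cohen r effect sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
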