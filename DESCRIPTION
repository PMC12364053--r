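Package: replanRL
Title: Deep Reinforcement Learning for Automated Proton-Therapy Replanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained simulator and library for studying reinforcement-
    learning-driven priority tuning in intensity-modulated proton therapy (IMPT)
    inverse planning. Provides synthetic voxelized phantom anatomies with target
    and organ-at-risk structures, Bragg-curve pencil-beam dose-influence matrices,
    weighted multi-objective fluence-map optimization by projected gradient
    descent, dose-volume-histogram computation with a 150-point clinical plan-
    quality score, a Markov-decision-process environment whose discrete actions
    adjust per-structure planning priorities, and Deep Q-Network and Proximal
    Policy Optimization agents trained per-phantom and evaluated on simulated
    anatomical change (tumor progression and regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
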