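Package: lapskill
Title: Skill Metrics and Synthetic Trajectories for Gesture-Based
    Laparoscopic Training Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A headless assessment engine for two-instrument minimally
    invasive surgery (MIS) skill tasks. Provides scene definitions for six
    classic box/VR-trainer tasks (grip and placement, transfer, bimanual
    traversal, instrument withdrawal and reinsertion, diathermy, and combined
    manipulation plus diathermy), reads and validates instrument-tip
    trajectory logs, detects contact, grasp, placement, clash, boundary and
    diathermy events against the scene, computes the standard five-parameter
    metric set (task time, per-hand efficiency of movement, economy of
    diathermy, weighted error tally) and the final score
    100 - sum(errors x values), and includes a seeded synthetic-trajectory
    simulator with fulcrum-constrained kinematics, skill profiles and an
    error-injection manifest for ground-truth testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
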