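Package: lapMotion
Title: Software-Based Video Motion Tracking for Surgical Skill Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tracks an instrument-tip point through laparoscopic video by
    normalized cross-correlation template matching, converts pixel
    trajectories to centimetres using two perpendicular reference lines of
    known real length, computes kinematic skill metrics (path length,
    average movement, speed, extreme-movement counts) with explicit
    handling of occluded frames, and compares expert versus novice cohorts
    with rank-based statistics. Includes a ground-truthed synthetic video
    generator so every pipeline stage can be validated without clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
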