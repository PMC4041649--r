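Package: mimizutrack
Title: Automated Tracking of Earthworm Posture, Body Length and Kinematics
    from Frame Sequences
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments a single earthworm from timed image sequences recorded
    in a circular dish, reduces the body to a one-pixel-wide centerline by
    Hilditch thinning, tracks the head, center and tail points across frames
    by nearest-endpoint association, and converts the trajectories into
    physical quantities: per-point velocities and elastic body length over
    time. Includes a synthetic worm generator with exported ground truth so
    that every pipeline stage can be benchmarked without real video, plus a
    command-line interface for tracking, synthesis, summarising and
    comparing trajectories against reference (manual) tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
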