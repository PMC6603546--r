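Package: skelrefine
Title: Constraint-Based Refinement of Depth-Camera Skeleton Sequences
Version: 0.1.0
Authors@R:
    person("skelrefine", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Cleans per-frame 3-D skeleton estimates produced by depth-camera
    SDKs (Kinect-style or Nuitrack-style joint sets). Stable per-bone
    reference lengths are estimated from an initialization window with
    angle-dependent and deviation-dependent weights, untrusted joints are
    detected from tracking states, bone-length deviations and motion
    implausibility, joint positions are predicted by a combined
    forward/backward second-order finite-difference scheme, and each frame
    is refined by a quasi-Newton energy minimization that enforces
    bone-length constancy and left/right symmetry. Includes a synthetic
    motion generator with an SDK-like corruption model and evaluation
    diagnostics (bone-length variance, prediction disagreement, symmetry
    error, ground-truth recovery).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
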