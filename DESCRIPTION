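Package: bellkin
Title: Corrected Bell Kinematics of Freely Swimming Jellyfish from In
    Situ Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Extracts two-dimensional bell kinematics of a freely swimming
    jellyfish from hand-held underwater video. Digitized exumbrella outlines
    are corrected for camera magnification (background reference-point
    tracking plus an arclength linear-fit adjustment) and for body roll about
    the optical axis, then smoothed and resampled into apex-rooted half
    profiles. The bell is discretized into a small number of segments by
    curvature analysis, anatomical landmarks, or error-minimizing node
    placement, and the segment kinematics are summarized with Fourier-series
    gait models, swimming-phase segmentation, node trajectory loops, and
    subumbrella volume estimates. A synthetic swimmer generator with a known
    camera model provides ground truth for validating every processing stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
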