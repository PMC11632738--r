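Package: facemetrics
Title: Automated Facial Anthropometry for Orthognathic Surgery Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automates the frontal soft-tissue facial analysis used in
    orthognathic surgery planning. A small convolutional network (an
    adaptation of the Tweaked landmark-regression architecture) localizes 13
    facial landmarks on centred 1024x1024 photographs, a 10 mm circular
    fiducial pad calibrates the pixel-to-millimetre scale, and nine
    Arnett/Bergman-style facial measurements (facial thirds, intercanthal
    distance, alar base, lip lengths, vermilion heights, interlabial gap)
    are derived in millimetres. Includes a procedural generator of schematic
    frontal faces with exact landmark ground truth for training and testing,
    and paired t-test agreement reports comparing automated against caliper
    measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    jpeg,
    png,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
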