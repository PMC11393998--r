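Package: bovimetry
Title: Non-Contact Cattle Body Measurement from Single-Side Depth Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes four standard cattle body dimensions (body height,
    lumbar height, body oblique length, chest girth) from a single side-view
    depth image and seven named 2-D keypoints. Keypoint depths are refined by
    conditional filtering against a Shoulder-Pin reference depth, lifted to
    3-D camera coordinates through the pinhole model, and the chest girth is
    estimated from an RBF-smoothed half profile completed by mirroring and a
    closed cubic spline. Includes keypoint-evaluation metrics (OKS, AP, mAP,
    MAE, MRE) and a parametric synthetic depth-scene generator with analytic
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
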