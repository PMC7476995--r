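Package: marrowdiff
Title: Digital Morphology Toolkit for Bone Marrow Smear Differential Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for automated bone marrow aspirate smear
    analysis: synthetic Wright-Giemsa-like field generation with per-cell
    ground truth, two-stage autofocus (grayscale-variance coarse search and
    Canny edge-fraction refinement), nucleated-cell localization and colour
    k-means segmentation, interpretable-feature 12-category cell
    classification with top-5 ranking, five-series differential reporting
    with the G:E ratio, and a method-comparison statistics suite
    (multiclass confusion metrics with binomial confidence intervals,
    two-way consistency intraclass correlation, Passing-Bablok regression
    with a cusum linearity test, and Bland-Altman limits of agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    ranger,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
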