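Package: cabbagemorph
Title: Non-Destructive Cabbage Morphometry from Instance Masks and Depth Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates cabbage head volume and total leaf area from
    top-down instance-segmentation masks combined with a co-registered
    depth raster. The hidden leaf-attachment point of each plant is
    recovered by robust (MSAC) per-leaf plane fitting and triple-plane
    intersection averaging; per-leaf 3D lengths then yield leaf areas
    through a length-based allometric rule, and the segmented head
    cross-section yields a sphere-model volume after pixel-to-metric
    conversion at the head equator. Includes COCO-style mask evaluation
    metrics (IoU, precision/recall, mAP over thresholds 0.50-0.95), a
    parametric synthetic scene generator with ground truth for end-to-end
    validation, and bundled reference tables from a field validation
    study of storage cabbage at three head-development growth stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
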