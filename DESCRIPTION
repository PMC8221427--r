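Package: tasselcv
Title: Patch-Based Maize Tassel Detection and Agricultural Detection Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A toolkit for detecting maize tassels in high-resolution aerial
    (UAV) RGB imagery and for scoring object detectors the way agricultural
    applications need. Implements deterministic tiling of raw frames into
    subimages and fixed-size patches with exact coordinate round-trips, a
    pluggable binary patch classifier with a lightweight reference
    implementation, the patch-based tassel detection pipeline that keeps
    tassel patches in colour and grayscales the rest, PASCAL VOC XML
    annotation I/O (LabelImg dialect), and a detection-to-ground-truth
    matching engine supporting both the default PASCAL protocol and a
    customized agricultural protocol (IoU threshold 0.3, score threshold 0.1,
    duplicate detections dropped rather than counted as false positives).
    Ships a seeded synthetic canopy generator so the whole pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    glmnet,
    grDevices,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
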