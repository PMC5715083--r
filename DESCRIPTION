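Package: glandbam
Title: Glandular Shape Aberrance and Tumour Grading via the Best Alignment Metric
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphometric grading of colorectal tissue from gland segmentation
    masks. Implements the Best Alignment Metric (BAM), a shape-space distance
    between planar closed curves minimizing squared mismatch over cyclic shift
    and rotation; the per-gland aberrance pipeline (minimum-area enclosing
    ellipse, whitening, unit-perimeter normalization, BAM against a circle);
    image-level aberrance features (mean BAM, BAM entropy, Regularity Index)
    with tangential-section and border-gland postprocessing; SVM-based two- and
    three-class grading with repeated stratified cross-validation, per-class
    metrics and ROC analysis; and a synthetic gland-mask generator with
    grade-controlled boundary deformation for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    EBImage,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    cluster,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
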