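Package: cloudlift
Title: Lifting 2D Instance Segmentations of Top-View RGB-D Frames into
    Per-Instance 3D Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mask-guided pipeline for turning 2D instance detections and
    segmentations of animals in top-view RGB-D frames into per-instance 3D
    point clouds via pinhole back-projection. Includes frame deduplication by
    double perceptual hashing (aHash + dHash), mosaic augmentation with
    annotation transforms, COCO-style detection/segmentation metrics
    (precision, AP, mAP over IoU 0.5:0.05:0.95, global pixel accuracy),
    point-to-point ICP registration with a cloud-similarity score, a
    pure-numeric Res2Net bottleneck forward pass, and a synthetic overhead
    RGB-D scene generator with exact ground truth for end-to-end validation.
    On-disk formats: 8-bit RGB and 16-bit depth PNG, ASCII PLY point clouds,
    Labelme-style polygon JSON, and YAML/JSON camera intrinsics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
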