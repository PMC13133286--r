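Package: ToolPoseKit
Title: Skeletal Pose Annotations and Keypoint Metrics for Surgical Instruments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Data model, format converters and evaluation metrics for
    skeletal pose annotations of minimally invasive surgical instruments.
    Provides S4 classes for four-keypoint tool skeletons
    (EntryPoint-HingePoint-Tip1-Tip2) with a three-state visibility taxonomy,
    parsing and serialization of the per-frame annotation JSON dialect and of
    COCO-style keypoint exports, keypoint-derived bounding boxes with margin
    and clipping, instance segmentation mask utilities (8/16-bit label PNG,
    instance removal), a tip-permutation-invariant Object Keypoint Similarity
    with a rotation-robust scale factor, COCO-protocol average precision and
    recall for poses and boxes, and a seeded synthetic endoscopic scene
    generator so that every component is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'keypoint.R'
    'pose.R'
    'bbox.R'
    'coco.R'
    'oks.R'
    'eval.R'
    'masks.R'
    'synthetic.R'
    'cli.R'
    'rawjson.R'
    'utils.R'
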