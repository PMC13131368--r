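Package: calfface
Title: Facial Keypoint Phenotyping for Dairy Calves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Post-detection analysis of facial keypoints in dairy calves:
    object keypoint similarity (OKS) evaluation of predicted against true
    keypoints with precision/recall/AP/AR/F1 across a threshold sweep, and
    extraction of welfare-related phenotypes (ear posture angle and
    forward/backward classification, time in position, ear-movement counts
    under a 20-consecutive-frame rule, eye opening and nostril distance in
    centimeters via ear-tag calibration). Includes readers and writers for
    COCO-keypoints JSON and YOLO pose text, group-aware dataset splitting,
    descriptive trait summaries, and a synthetic calf-head keypoint
    generator with two-state Markov ear dynamics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
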