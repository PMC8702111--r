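Package: laryngotrack
Title: Quantitative Laryngeal Elevation from Videofluoroscopic Swallowing Study Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures laryngeal elevation from per-frame instance segmentations
    of lateral-view videofluoroscopic swallowing study (VFSS) video. Tracks the
    midpoint of the thyroid cartilage and vocal fold complex (TVC) relative to
    the C1 spinous process, selects the swallow event as the longest upward
    excursion of the relative trajectory, converts pixel displacement to
    millimeters with per-axis radiographic calibration factors, and evaluates
    segmentation quality by intersection over union (IoU) and recall at a
    configurable cutoff. Includes a synthetic fluoroscopy phantom generator
    with exact ground-truth masks and kinematics, controlled mask degradation
    to a target IoU, a geometric augmentation pipeline, and a classical
    threshold-based segmenter, so the full measurement chain is testable
    without patient data or a trained network.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    png,
    igraph,
    EBImage,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
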