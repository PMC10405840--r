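Package: sonoquant
Title: Quantification Pipelines for Focused-Ultrasound Blood-Brain-Barrier
    Opening Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-quantification pipelines used in preclinical and clinical
    studies of focused-ultrasound (FUS) induced blood-brain-barrier opening:
    contrast-enhanced MRI opening volumetry with reference normalization and
    per-slice active contours; a structural algorithm measuring the length of
    tau-affected neuronal processes on confocal images (k-means intensity
    segmentation, circular Hough soma detection, skeletonization, geodesic
    path tracing, longest-5% averaging) with a Monte-Carlo pairwise-difference
    CDF comparison between groups; amyloid-plaque population and volume
    quantification; and amyloid-PET SUVr change over a caller-supplied region
    label volume.  A synthetic phantom generator provides MR, confocal and PET
    inputs with exact ground truth so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
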