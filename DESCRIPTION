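Package: wormtracker
Title: Detection, Identity Tracking and Activity Extraction of Head-Ganglion
    Neurons in Freely Behaving C. elegans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A bottom-up pipeline for whole-brain calcium imaging of the
    Caenorhabditis elegans head ganglion in freely behaving animals. From a
    4D two-channel fluorescence recording it segments the head and builds the
    worm-intrinsic anterior-posterior / ventral-dorsal coordinate system,
    detects 2D neuronal regions per frame with an anchor-box detector and
    learned bounding-box corrections, merges regions into 3D neurons by
    maximum-weight bipartite matching across adjacent frames with an
    intensity-profile split rule, assigns consistent digital identities per
    volume with a metric-learning classifier trained under a combined
    angular-margin softmax loss, and extracts ratiometric GCaMP/RFP activity
    traces. Includes a ground-truthed synthetic volume generator emulating a
    deforming worm head so every stage is trainable and testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    clue,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
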