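Package: myelinseg
Title: Axon, Inner Tongue and Compact Myelin Segmentation and G-Ratio
    Morphometry for Electron Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments each myelinated-fibre cross-section in transmission
    electron microscopy images into axon, inner tongue and compact myelin
    using a two-pass (autocontext) random-forest pixel classifier, an
    object classifier over axoplasm instance candidates, and a three-stage
    seeded region-growing pipeline (inner-region detection, fibre
    expansion, axon selection).  Builds a fibre to inner-region to axon
    hierarchy, computes per-fibre myelin and axon g-ratios and inner
    tongue metrics, and evaluates instance segmentations with F1 over an
    IoU threshold range, Lin's concordance correlation coefficient and
    Bland-Altman agreement.  Includes a synthetic phantom generator with
    exact analytic ground truth so the full pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
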