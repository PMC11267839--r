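Package: sproutscan
Title: Lightweight Seed-Germination Detection and Vitality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for non-destructive, image-based monitoring of seed
    germination in multi-cell culture dishes. Provides composable building
    blocks of a lightweight anchor-free object detector (depthwise-separable
    backbone, cross-scale feature fusion neck, online re-parameterization
    blocks, focal modulation, asymmetric dual detection head) with exact
    parameter and FLOP accounting, Gaussian soft non-maximum suppression,
    precision/recall/mAP evaluation against PASCAL VOC annotations, a
    synthetic dish-image generator with per-seed germination schedules, and
    computation of germination rate, germination energy and germination
    index time series over salinity-by-nanoparticle treatment designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
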