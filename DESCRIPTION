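Package: penseg
Title: Panoptic Segmentation of Individual Animals in Overhead Pen Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ellipse-based panoptic segmentation of individual animals (e.g. pigs)
    in top-down pen images. Provides ellipse annotation with head orientation and
    camera-depth ordering, rendering of per-pixel training targets (binary,
    three-class distance, body-part and instance maps), the binary, categorical
    and discriminative pixel-embedding training objectives, a small configurable
    encoder-decoder network with skip connections and swappable heads, HDBSCAN
    based instance clustering with direct least-squares ellipse extraction and
    head-side orientation recovery, panoptic-quality evaluation, and a
    deterministic synthetic scene generator so the full pipeline can be exercised
    end to end without the original footage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
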