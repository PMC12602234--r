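Package: xalign
Title: Explanation-Fidelity Scoring for Medical-Image Saliency Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how well a classifier's saliency map agrees with an
    expert-annotated lesion mask. Implements the XAlign score and its three
    components (weighted relevance overlap, boundary agreement via Hausdorff
    contour distance, and a dispersion penalty), the native explanation-head
    pipeline that turns a convolutional activation stack into a binary
    heatmap (top-k channel aggregation, min-max normalisation, fixed /
    percentile / Otsu thresholding, nearest-neighbour upscaling), a forward
    simulator for integrate-and-fire spiking layers, a seeded phantom
    generator that produces masks and saliency maps of controlled alignment
    quality, and an evaluation harness with dataset-level aggregation,
    exact paired Wilcoxon signed-rank tests, and weight / parameter
    sensitivity grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
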