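Package: swincount
Title: Tree Counting in Overhead Imagery with a Shifted-Window Transformer U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects and counts individual tree crowns in overhead RGB
    imagery by density-map regression with a U-shaped encoder-decoder built
    from shifted-window multi-head self-attention blocks.  Includes centroid
    point-annotation handling, density-map supervision targets, the counting
    metrics (overall accuracy, omission, commission and estimation error),
    a seeded synthetic-orchard generator with exact ground truth, and a
    self-contained SGD training loop with hand-derived backpropagation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    EBImage,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
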