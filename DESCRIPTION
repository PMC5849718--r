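Package: phenoseg
Title: Unsupervised Conditional Random Field Segmentation of Greenhouse Plant Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised segmentation of greenhouse plant images into fruit,
    leaf and background regions without any labelled training data. Per-pixel
    filter-bank descriptors are quantized into visual words by a K-means
    codebook, overlapping spatial regions act as documents for latent
    Dirichlet allocation fitted by collapsed Gibbs sampling, and the resulting
    per-pixel topic posterior supplies the unary potential of a fully
    connected conditional random field refined by mean-field inference. A
    coarse-to-fine variant runs the same pipeline over a three-level image
    pyramid, propagating each level's labelling to the next as a soft
    annotation prior. Includes a synthetic greenhouse-scene generator with
    pixel-exact ground truth, colour-statistics class naming, fruit
    extraction, and pixel-accuracy / over- and under-segmentation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jpeg,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
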