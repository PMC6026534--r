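Package: msbslda
Title: Unsupervised Plant Image Segmentation with Mean-Shift Bandwidth
    Searching Latent Dirichlet Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised scene and leaf segmentation for plant phenotyping
    images. Builds filter-bank visual words, assigns them to spatial
    documents (non-overlapping or overlapping rectangles, SLIC super-pixels,
    or mean-shift mode clusters with automatic joint-bandwidth search) and
    fits a collapsed-Gibbs latent Dirichlet allocation topic model to
    produce semantic label maps. Includes plant foreground extraction,
    fruit removal, illumination diagnosis and homomorphic correction,
    marker-controlled watershed leaf instance segmentation, the standard
    segmentation evaluation metrics (segmentation accuracy, over- and
    under-segmentation rates, Dice, symmetric best Dice, difference in
    count, modified Hausdorff distance), synthetic scene and corpus
    generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    digest,
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
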