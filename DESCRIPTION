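Package: nucleiclust
Title: Cluster Analysis of Cell Nuclei in H&E Histopathology Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of cell-nucleus spatial architecture in
    hematoxylin-and-eosin (H&E) stained histopathology patches. Provides
    modified-LAB stain normalization and optical-density stain deconvolution,
    marker-controlled watershed nuclei segmentation, minimum-spanning-tree
    (MST) cluster analysis of nucleus centroids with inconsistent-edge
    removal, a fixed 26-feature cluster descriptor, majority-voting feature
    selection combining four filter and three wrapper methods, and both
    supervised (stacking ensemble) and unsupervised (k-medoids) grade
    classification, together with a synthetic H&E-like patch and feature
    table generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    grDevices,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    png,
    jsonlite,
    FNN,
    cluster,
    glmnet,
    digest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
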