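Package: colorpart
Title: Well-Formedness Analysis of Color-Space Partitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether natural-language color categorizations
    correspond to optimal partitions of a Munsell-style chip palette embedded in
    CIELAB space.  Implements the well-formedness objective W = S + D (within-
    category similarity plus between-category dissimilarity, with similarity
    exp(-0.001 d^2) of CIELAB distance), three W-maximization procedures
    (particle swarm optimization over category centroids, greedy chip
    reassignment, and a k-medoids baseline), six external cluster-comparison
    indices (ARI, NMI, VI, split/join, Jaccard, Fowlkes-Mallows), random-Voronoi
    and hue-rotation null models, Page's trend test for ordered ensembles, and a
    synthetic generator of Munsell-like chip grids with planted naming systems
    so every stage runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    grDevices,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
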