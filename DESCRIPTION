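Package: decoyclust
Title: Comparison and Clustering of Protein Structure Decoys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: High-throughput comparison of protein models on C-alpha
    coordinates with six similarity measures (coordinate RMSD via a
    closed-form covariance eigenvalue solution, distance RMSD, GDT_TS,
    TM-score, MaxSub and contact-map overlap), all-versus-all and
    versus-reference similarity matrices, K-means and hierarchical
    agglomerative clustering of the resulting distance matrices, and
    representative-model selection by the min(<R>/f) criterion. Includes
    a deterministic synthetic decoy-ensemble generator with planted
    clusters and a command-line front end for multi-model PDB files and
    one-column list files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    generics,
    rlang,
    ggplot2,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    igraph,
    mclust,
    jsonlite
Config/testthat/edition: 3
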