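Package: nashpdc
Title: Protein Complex Detection in Interaction Networks by a Sequential
    Coalition Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects protein complexes in protein-protein interaction (PPI)
    networks by playing a sequential non-cooperative coalition-formation game
    whose Nash equilibria are partial dense vertex covers: disjoint vertex
    subsets that each satisfy a degree-density floor, an edge-density floor
    and a diameter bound, and are locally maximal. Provides readers and
    writers for edge-list and complex-membership files, planted-partition
    (Girvan-Newman) and Erdos-Renyi benchmark generators with ground truth,
    edge-rewiring perturbation, and clustering quality metrics: normalized
    mutual information, Jaccard matching score, complex-wise sensitivity,
    positive predictive value and accuracy, and connectivity density.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    purrr,
    rlang,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
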