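Package: aquascan
Title: Genome-Wide Characterization of Plant Aquaporins from Sequence to
    Co-Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for genome-wide characterization of plant
    aquaporin (major intrinsic protein, MIP) families: candidate screening by
    NPA motifs, transmembrane-helix counts and length, residue-signature
    extraction (NPA boxes, ar/R selectivity filter, Froger positions),
    homology-based subfamily classification and systematic naming, rule-based
    substrate-specificity prediction, Nei-Gojobori Ka/Ks selection tests,
    FPKM and 2^-ddCt expression processing with hierarchical expression
    grouping, and percentile-thresholded Pearson co-expression networks.
    Includes a seeded synthetic-data generator that plants ground truth for
    every stage so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    generics,
    ggplot2,
    igraph,
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
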