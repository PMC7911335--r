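Package: homodist
Title: Distance-Ordered Homoplasy Tracing for Species Delimitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the HomoDist procedure for studying how parsimony
    homoplasy accumulates as taxa are added to a phylogenetic tree in order
    of evolutionary distance from a central taxon. Starting from an aligned
    set of DNA sequences (e.g. ITS or LSU D1/D2 rDNA), the package computes
    pairwise F84 distances, orders taxa by distance from an automatically
    selected or user-chosen center, and at each addition step builds
    neighbor-joining and UPGMA trees and scores the consistency index (CI),
    retention index (RI), homoplasy index (HI = 1 - CI) and the
    distance-normalized specific homoplasy index (SHI = HI / maximum
    pairwise distance). Downstream analyses locate the first appearance of
    homoplasy along the series, correlate CI with distance, and partition
    taxa into groups of constant HI as auxiliary evidence for species
    delimitation. A synthetic-data module generates alignments with known,
    controllable homoplasy for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
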