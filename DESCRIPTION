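Package: petsv
Title: Structural Variant Discovery from DNA Paired-End-Tag Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for detecting genomic structural variants from mapped
    DNA paired-end-tag (mate-pair) libraries with large insert sizes.
    Classifies paired tags as concordant or discordant against a library
    span model, clusters discordant pairs around fusion points, types
    clusters as deletions, tandem duplications, inversions, unpaired
    inversions, translocations and eight insertion sub-types, separates
    isolated from complex events through breakpoint superclustering,
    matches calls across libraries of different insert sizes, estimates
    copy number from physical fragment coverage and reconstructs focally
    amplified regions by fusion-point-guided concatenation of contig
    graphs. A coordinate-level simulator of rearranged genomes and
    size-selected tag libraries provides ground truth for benchmarking.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
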