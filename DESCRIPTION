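Package: synologr
Title: Detection and Quantification of Highly Similar Intra-Genome Homologs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects synologs (intra-genome homologs arising from gene
    duplication or horizontal transfer) in prokaryotic proteomes by exhaustive
    pairwise protein alignment with identity and coverage thresholds, or by
    shared protein-family labels. Builds synolog groups as connected
    components of passing pairs, computes per-genome and cohort statistics
    (synolog fractions, median/MAD outlier thresholds, count-group
    regressions), classifies tandem versus dispersed genomic arrangements,
    profiles the functional categories of neighbouring genes, and simulates
    proteomes with planted duplicate groups for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
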