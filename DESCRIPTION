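Package: plastidkit
Title: Chloroplast Genome Finishing, Validation and Comparative Analysis
Version: 0.1.0
Authors@R: person("Plastid", "Kit Developers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for finishing quadripartite chloroplast genomes from draft
    contigs and for downstream comparative analysis. Stitches LSC, SSC and
    inverted-repeat contigs via junction suffix-prefix overlaps, detects the
    inverted repeat pair, validates assemblies by stringency-controlled short
    read remapping and coverage screening, and provides native implementations
    of dispersed-repeat search with Hamming tolerance, microsatellite scanning
    with MISA-style thresholds, pseudogene detection by internal stop codons,
    inverted-repeat boundary and expansion analysis, pairwise whole-genome
    variant counting, and detection of mitochondrion-derived inserts. Includes
    a deterministic synthetic plastome generator so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
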