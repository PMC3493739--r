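Package: srnaprofiler
Title: Small RNA Profiling of Two-Condition miRNA Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of two small-RNA sequencing libraries
    (case versus control): adapter trimming and tag collapsing, exact-match
    genome mapping with a priority annotation cascade, stem-loop based novel
    miRNA candidate calling, Audic-Claverie differential expression of known
    miRNAs with RPM normalization and Benjamini-Hochberg correction,
    rule-based miRNA target prediction with a duplex minimum-free-energy
    ratio criterion, and hypergeometric GO-term enrichment of predicted
    targets. Includes a synthetic-data generator with machine-readable
    ground truth so the whole pipeline is testable without external
    downloads, and transcriptions of the reference result tables used for
    arithmetic self-checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
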