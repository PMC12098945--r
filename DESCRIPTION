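Package: univgroups
Title: Universal Conserved Gene Groups from Multi-Species Peptide Sets
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds groups of highly conserved protein-coding genes that are
    universal across a clade (exactly one member per species) starting from
    per-species peptide sets and ortholog tables from two reference species.
    Group membership is optimized against profile models built from multiple
    alignments and scored with a consensus-normalized relative score R;
    missing gene models are rescued from genomic sequence; and each group's
    taxon-specificity is graded with the S statistic at three taxonomic
    depths. Includes a deterministic synthetic-data generator so every
    pipeline stage can be exercised without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
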