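Package: fechmotif
Title: Genomic Survey of [2Fe-2S] Cluster Motifs in Ferrochelatases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to survey iron-sulfur ([2Fe-2S]) cluster cysteine motifs
    across the ferrochelatase protein family: FASTA and genome-metadata
    ingestion with genus/order-level genome paring, catalytic-histidine
    verification by global alignment to a reference ferrochelatase, region
    annotation (N-terminal extension, internal insertion, C-terminal tail),
    PROSITE-subset motif scanning with motif-containing-ferrochelatase (MCF)
    calling, cysteine/motif statistics including binned motif likelihoods and
    binary logistic regression fit by iteratively reweighted least squares,
    physiology cross-tabulations, and distance-based phylogeny (Jukes-Cantor
    corrected distances, neighbor joining, bootstrap, majority-rule
    consensus). A synthetic-data generator plants regions, motifs and
    metadata associations so every pipeline stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    optparse
Config/testthat/edition: 3
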