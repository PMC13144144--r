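Package: MotifColoc
Title: Peak Co-Localization and Degenerate Motif Enrichment for ChIP-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing co-localization of two ChIP-seq peak sets
    and the sequence features of their shared loci. Peaks are reduced to
    coverage summits, expanded to symmetric windows, and classified into
    shared clusters by interval overlap. Shared-locus sequences are scored
    for degenerate consensus patterns (fixed and N positions, with a
    mismatch allowance restricted to fixed positions) and enrichment over
    background windows is assessed with two-sided Fisher's exact tests and
    cross-product odds ratios. A dinucleotide-preserving permutation test
    (exact-count Eulerian-trail shuffling) yields empirical p-values of the
    form (r+1)/(n+1) that control for local nucleotide composition.
    Summit-centered and length-scaled coverage matrices support heatmap
    style visualisation, and a synthetic-data generator produces genomes,
    peak/coverage fixtures and motif-planted sequence sets with ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Sequencing, ChIPSeq, MotifDiscovery, Coverage, Software
RoxygenNote: 7.3.3
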