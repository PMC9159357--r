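Package: apastab
Title: Stability Analysis of Alternative Polyadenylation Isoforms from
    3'-End Sequencing of Metabolically Labeled RNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for poly(A)+ RNA stability measured by 3'-end
    sequencing of 4-thiouridine-labeled (newly made) versus flow-through
    (pre-existing) RNA fractions. Calls polyadenylation-site (PAS) reads from
    alignments by their non-genomic 5' T soft-clips, clusters cleavage sites
    within 24 nt, assigns clusters to genes and regions (terminal exon versus
    intron), normalizes counts by the median-ratio method, computes per-PAS
    Stability Scores log2(FT/4sU) with ANOVA tests for differential stability
    across conditions, quantifies 3'UTR and intronic alternative-polyadenylation
    isoform usage and stability (relative expression, RED, delta-SS, Fisher
    exact tests), ranks sequence and architecture features by individual and
    cumulative R-squared, tests hexamer enrichment between gene sets, and scores
    3'UTR secondary-structure propensity by windowed minimum folding energy and
    Gini indices. Includes a synthetic-data generator with known first-order
    decay kinetics so every stage is verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    DESeq2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
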