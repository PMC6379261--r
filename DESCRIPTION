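Package: taxongauge
Title: Genome-Based Taxonomy for Closely Related Bacterial Genera
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Whole-genome taxonomic delineation of closely related bacterial
    genera, built around the workflow used to disentangle Cupriavidus and
    Ralstonia. Implements fragment-based two-way average nucleotide identity
    (ANI) with a seeded banded Smith-Waterman aligner, percentage of conserved
    proteins (POCP) with a 60 percent genus boundary, tetranucleotide-signature
    principal component analysis, distance-based marker-gene phylogenetics
    (16S rRNA and four-gene MLSA) with bootstrap support, UPGMA clustering of
    (1 - ANI) distances with context-specific species thresholds, degenerate
    replication-motif scanning, per-replicon COG category comparison by
    Fisher's exact test with Benjamini-Hochberg correction, and a consensus
    decision engine that combines all lines of evidence into genus and species
    reclassification proposals. A seeded synthetic-genome simulator generates
    panels with planted identity, ortholog and clade structure so that every
    stage of the pipeline can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
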