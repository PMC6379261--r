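#' Replicon summary of the NH9 reference genome
#'
#' Published per-replicon statistics of the C. necator NH9 complete genome
#' (two chromosomes and two plasmids, accessions CP017757-CP017760):
#' length, GC percent and annotated CDS count. These printed values serve
#' as inputs for whole-genome bookkeeping checks without downloading the
#' assembly; [genomeStats()] computes the same quantities from sequence.
#'
#' @return data.frame with columns `replicon`, `accession`, `length_bp`,
#'   `gc_percent`, `cds_count`.
#' @export
nh9RepliconSummary <- function() {
    path <- system.file("extdata", "nh9_replicon_summary.tsv",
                        package = "taxongauge", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
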