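#' @importFrom Biostrings oligonucleotideFrequency
#' @importFrom stats prcomp hclust cutree dist setNames
NULL

#' Tetranucleotide profile of a genome
#'
#' Counts all 256 DNA 4-mers in sliding windows (length 4, step 1) over the
#' forward strand of every contig; windows containing any non-ACGT character
#' are skipped, counts are summed over contigs and normalised to
#' frequencies. With `both_strands = TRUE` the counts of each window and its
#' reverse complement are summed (off by default, matching the common
#' forward-strand convention of k-mer composition tools).
#'
#' @param genome a [GenomeRecord-class].
#' @param both_strands add reverse-complement counts.
#' @return a [TetraProfile-class].
#' @export
tetraProfile <- function(genome, both_strands = FALSE) {
    stopifnot(methods::is(genome, "GenomeRecord"))
    ctg <- Biostrings::DNAStringSet(toupper(as.character(genome@contigs)))
    counts <- colSums(Biostrings::oligonucleotideFrequency(ctg, width = 4))
    if (both_strands)
        counts <- counts + colSums(Biostrings::oligonucleotideFrequency(
            Biostrings::reverseComplement(ctg), width = 4))
    if (sum(counts) == 0)
        stop("no countable windows in genome '", genome@strainId, "'")
    methods::new("TetraProfile", strainId = genome@strainId,
        counts = stats::setNames(as.integer(counts), names(counts)),
        frequencies = counts / sum(counts))
}

#' Principal component embedding of tetranucleotide frequencies
#'
#' Stacks the 256-long frequency vectors into a genomes x 256 matrix,
#' column-centres it (no scaling to unit variance) and decomposes it by
#' singular values. Scores are the projections on the first `k` components.
#'
#' @param profiles list of [TetraProfile-class] objects (>= 3).
#' @param k number of components to retain (default 3).
#' @return a [PCAEmbedding-class].
#' @export
pcaEmbed <- function(profiles, k = 3L) {
    if (length(profiles) < 3) stop("need at least 3 profiles")
    X <- do.call(rbind, lapply(profiles, tetraFrequencies))
    rownames(X) <- vapply(profiles, strainId, character(1))
    k <- min(as.integer(k), nrow(X) - 1L, ncol(X))
    p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    v <- p$sdev^2 / sum(p$sdev^2)
    methods::new("PCAEmbedding",
        scores = p$x[, seq_len(k), drop = FALSE],
        explainedVariance = v[seq_len(k)],
        fullVariance = v,
        loadings = t(p$rotation[, seq_len(k), drop = FALSE]))
}

# internal: size-descending, first-seen stable cluster relabelling -> A, B, ...
.letterLabels <- function(membership) {
    ids <- names(membership)
    sizes <- table(membership)
    first <- vapply(names(sizes), function(cl) which(membership == cl)[1], integer(1))
    ord <- names(sizes)[order(-as.integer(sizes), first)]
    labs <- c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))[seq_along(ord)]
    stats::setNames(labs[match(as.character(membership), ord)], ids)
}

#' Cluster genomes on their PCA scores
#'
#' Average-linkage hierarchical clustering on the Euclidean distance of the
#' component scores, cut at `linkage_cut`; clusters are labelled `A`, `B`,
#' ... by decreasing size (ties broken by first-seen strain order).
#'
#' @param embedding a [PCAEmbedding-class].
#' @param linkage_cut height at which the dendrogram is cut.
#' @return named character vector: strain id -> cluster label.
#' @export
clusterEmbedding <- function(embedding, linkage_cut) {
    sc <- pcaScores(embedding)
    if (nrow(sc) == 1) return(stats::setNames("A", rownames(sc)))
    hc <- stats::hclust(stats::dist(sc), method = "average")
    .letterLabels(stats::cutree(hc, h = linkage_cut))
}
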