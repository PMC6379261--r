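#' @import methods
#' @importFrom Biostrings DNAStringSet AAStringSet
NULL

#' GenomeRecord: a strain's assembly plus taxonomic metadata
#'
#' Container for one genome assembly: an ordered set of contig sequences
#' together with the strain's current classification. All downstream
#' whole-genome comparisons (ANI, tetranucleotide profiling, motif scans)
#' take a `GenomeRecord`.
#'
#' @slot strainId single character, non-empty strain identifier.
#' @slot contigs a [Biostrings::DNAStringSet] with one entry per contig.
#' @slot currentGenus,currentSpecies current classification labels; species
#'   `"sp."` denotes a strain unassigned at species level.
#' @slot typeStrain logical flag: is this the nomenclatural type strain of
#'   its species?
#' @slot phylotype optional phylotype label (`NA_character_` when absent).
#'
#' @seealso [genomeRecord()] for the user-facing constructor.
#' @exportClass GenomeRecord
setClass("GenomeRecord",
    representation(
        strainId = "character",
        contigs = "DNAStringSet",
        currentGenus = "character",
        currentSpecies = "character",
        typeStrain = "logical",
        phylotype = "character"
    )
)

setValidity("GenomeRecord", function(object) {
    msg <- character()
    if (length(object@strainId) != 1L || !nzchar(object@strainId))
        msg <- c(msg, "strainId must be a single non-empty string")
    if (length(object@contigs) < 1L)
        msg <- c(msg, "a genome needs at least one contig")
    if (length(object@contigs) >= 1L && sum(Biostrings::width(object@contigs)) == 0)
        msg <- c(msg, "total genome length must be > 0")
    if (length(msg)) msg else TRUE
})

#' ProteomeRecord: a strain's predicted protein set
#'
#' @slot strainId single character strain identifier.
#' @slot proteins a [Biostrings::AAStringSet], one entry per protein.
#'
#' @seealso [proteomeRecord()]
#' @exportClass ProteomeRecord
setClass("ProteomeRecord",
    representation(strainId = "character", proteins = "AAStringSet")
)

setValidity("ProteomeRecord", function(object) {
    msg <- character()
    if (length(object@strainId) != 1L || !nzchar(object@strainId))
        msg <- c(msg, "strainId must be a single non-empty string")
    if (length(object@proteins) < 1L)
        msg <- c(msg, "a proteome needs at least one protein")
    if (length(msg)) msg else TRUE
})

#' ANIMatrix: symmetric matrix of two-way average nucleotide identities
#'
#' Percent identities for all strain pairs; the diagonal is 100 by
#' construction and both orientations of a pair store the same two-way value.
#' Pairs with no qualifying alignment signal are `NA` and are refused by
#' downstream clustering.
#'
#' @slot values numeric percent matrix with strain ids as dimnames.
#'
#' @exportClass ANIMatrix
setClass("ANIMatrix", representation(values = "matrix"))

setValidity("ANIMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
    if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
        msg <- c(msg, "row and column names must both give the strain order")
    if (nrow(v) > 0 && any(abs(diag(v) - 100) > 1e-9))
        msg <- c(msg, "diagonal must be 100")
    ok <- !is.na(v) & !is.na(t(v))
    if (any(abs(v[ok] - t(v)[ok]) > 1e-9)) msg <- c(msg, "matrix must be symmetric")
    if (length(msg)) msg else TRUE
})

#' TetraProfile: 256-long tetranucleotide count/frequency vector
#'
#' Counts of all `4^4 = 256` DNA 4-mers in lexicographic `A < C < G < T`
#' order (forward strand, ambiguous windows skipped) and the corresponding
#' frequencies summing to one.
#'
#' @slot strainId strain identifier.
#' @slot counts integer vector of length 256, named by 4-mer.
#' @slot frequencies numeric vector of length 256 summing to 1.
#'
#' @exportClass TetraProfile
setClass("TetraProfile",
    representation(strainId = "character", counts = "integer",
                   frequencies = "numeric")
)

setValidity("TetraProfile", function(object) {
    msg <- character()
    if (length(object@counts) != 256L) msg <- c(msg, "counts must have length 256")
    if (length(object@frequencies) != 256L)
        msg <- c(msg, "frequencies must have length 256")
    if (sum(object@counts) > 0 && abs(sum(object@frequencies) - 1) > 1e-9)
        msg <- c(msg, "frequencies must sum to 1")
    if (length(msg)) msg else TRUE
})

#' PCAEmbedding: principal-component scores of genome signatures
#'
#' @slot scores n x k numeric score matrix, rows named by strain.
#' @slot explainedVariance fraction of variance carried by each of the first
#'   k components.
#' @slot fullVariance fractions for all `min(n - 1, p)` components (sums to 1).
#' @slot loadings k x p component loading matrix (rows orthonormal).
#'
#' @exportClass PCAEmbedding
setClass("PCAEmbedding",
    representation(scores = "matrix", explainedVariance = "numeric",
                   fullVariance = "numeric", loadings = "matrix")
)

setValidity("PCAEmbedding", function(object) {
    msg <- character()
    if (ncol(object@scores) != length(object@explainedVariance))
        msg <- c(msg, "one explained-variance fraction per score column")
    if (any(diff(object@explainedVariance) > 1e-9))
        msg <- c(msg, "explained variance fractions must be non-increasing")
    if (abs(sum(object@fullVariance) - 1) > 1e-6)
        msg <- c(msg, "full variance fractions must sum to 1")
    if (length(msg)) msg else TRUE
})
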