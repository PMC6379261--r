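#' Accessors for taxongauge classes
#'
#' `strainId()` returns the strain identifier; `contigs()` the contig
#' [Biostrings::DNAStringSet] of a [GenomeRecord]; `proteins()` the
#' [Biostrings::AAStringSet] of a [ProteomeRecord]; `aniValues()` the raw
#' percent matrix of an [ANIMatrix]; `tetraFrequencies()` and `tetraCounts()`
#' the 4-mer vectors of a [TetraProfile]; `pcaScores()` and
#' `explainedVariance()` the components of a [PCAEmbedding].
#'
#' @param x an object of the appropriate class.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("strainId", function(x) standardGeneric("strainId"))

#' @rdname accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @rdname accessors
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname accessors
#' @export
setGeneric("aniValues", function(x) standardGeneric("aniValues"))

#' @rdname accessors
#' @export
setGeneric("tetraFrequencies", function(x) standardGeneric("tetraFrequencies"))

#' @rdname accessors
#' @export
setGeneric("tetraCounts", function(x) standardGeneric("tetraCounts"))

#' @rdname accessors
#' @export
setGeneric("pcaScores", function(x) standardGeneric("pcaScores"))

#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname accessors
setMethod("strainId", "GenomeRecord", function(x) x@strainId)

#' @rdname accessors
setMethod("strainId", "ProteomeRecord", function(x) x@strainId)

#' @rdname accessors
setMethod("strainId", "TetraProfile", function(x) x@strainId)

#' @rdname accessors
setMethod("contigs", "GenomeRecord", function(x) x@contigs)

#' @rdname accessors
setMethod("proteins", "ProteomeRecord", function(x) x@proteins)

#' @rdname accessors
setMethod("aniValues", "ANIMatrix", function(x) x@values)

#' @rdname accessors
setMethod("tetraFrequencies", "TetraProfile", function(x) x@frequencies)

#' @rdname accessors
setMethod("tetraCounts", "TetraProfile", function(x) x@counts)

#' @rdname accessors
setMethod("pcaScores", "PCAEmbedding", function(x) x@scores)

#' @rdname accessors
setMethod("explainedVariance", "PCAEmbedding", function(x) x@explainedVariance)

setMethod("show", "GenomeRecord", function(object) {
    w <- Biostrings::width(object@contigs)
    cat("GenomeRecord", object@strainId, "\n")
    cat("  ", length(w), " contig(s), ", format(sum(w), big.mark = ","),
        " bp total\n", sep = "")
    cat("  current name: ", object@currentGenus, " ", object@currentSpecies,
        if (isTRUE(object@typeStrain)) " (type strain)" else "", "\n", sep = "")
    if (!is.na(object@phylotype))
        cat("  phylotype: ", object@phylotype, "\n", sep = "")
})

setMethod("show", "ProteomeRecord", function(object) {
    cat("ProteomeRecord", object@strainId, "\n")
    cat("  ", length(object@proteins), " proteins\n", sep = "")
})

setMethod("show", "ANIMatrix", function(object) {
    n <- nrow(object@values)
    cat("ANIMatrix over", n, "strains\n")
    off <- object@values[upper.tri(object@values)]
    if (length(off)) {
        cat(sprintf("  pairwise ANI range: %.2f - %.2f%% (%d NA)\n",
                    suppressWarnings(min(off, na.rm = TRUE)),
                    suppressWarnings(max(off, na.rm = TRUE)),
                    sum(is.na(off))))
    }
})

setMethod("show", "TetraProfile", function(object) {
    cat("TetraProfile", object@strainId, ":", sum(object@counts),
        "counted 4-mer windows\n")
})

setMethod("show", "PCAEmbedding", function(object) {
    cat("PCAEmbedding:", nrow(object@scores), "genomes x",
        ncol(object@scores), "components\n")
    cat("  explained variance:",
        paste(sprintf("%.1f%%", 100 * object@explainedVariance), collapse = ", "),
        "\n")
})
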