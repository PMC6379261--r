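#' @importFrom Biostrings readDNAStringSet readAAStringSet writeXStringSet
#'   width alphabetFrequency
#' @importFrom ape read.tree write.tree
NULL

IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N", "-", ".")
IUPAC_AA <- c(LETTERS, "*", "-", ".")

#' Read a FASTA file into a list of sequence records
#'
#' One record per header line; wrapped sequence lines are collapsed. Case is
#' preserved on read (all comparisons elsewhere in the package are
#' case-insensitive, so soft-masked lowercase stretches are treated like any
#' other sequence).
#'
#' @param path path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`; residues outside the IUPAC
#'   alphabet (ambiguity codes included) raise an error naming the record.
#' @return a list of records, each `list(id, description, sequence)`.
#' @export
readFasta <- function(path, alphabet = c("nucleotide", "protein")) {
    alphabet <- match.arg(alphabet)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) stop("empty FASTA file: ", path)
    if (!startsWith(lines[[1]], ">"))
        stop("malformed FASTA (no '>' header): ", path)
    hdr <- grepl("^>", lines)
    rec_idx <- cumsum(hdr)
    headers <- sub("^>", "", lines[hdr])
    ids <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers),
                   sub("^\\S+\\s+", "", headers), "")
    seqs <- vapply(split(lines[!hdr], rec_idx[!hdr]),
                   paste0, character(1), collapse = "")
    seqs <- unname(seqs[as.character(seq_along(ids))])
    seqs[is.na(seqs)] <- ""
    allowed <- if (alphabet == "nucleotide") IUPAC_NT else IUPAC_AA
    for (i in seq_along(ids)) {
        if (!nzchar(ids[[i]])) stop("record ", i, " has an empty id")
        if (!nzchar(seqs[[i]])) stop("record '", ids[[i]], "' has an empty sequence")
        chars <- unique(strsplit(toupper(seqs[[i]]), "")[[1]])
        bad <- setdiff(chars, allowed)
        if (length(bad))
            stop("record '", ids[[i]], "' contains characters outside the ",
                 alphabet, " alphabet: ", paste(bad, collapse = ", "))
    }
    mapply(function(id, d, s) list(id = id, description = d, sequence = s),
           ids, desc, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records list of `list(id, description, sequence)` records (as
#'   returned by [readFasta()]), or a named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(records, path, width = 70L) {
    if (is.character(records))
        records <- mapply(function(id, s) list(id = id, description = "", sequence = s),
                          names(records), records, SIMPLIFY = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    for (r in records) {
        hdr <- if (nzchar(r$description %||% "")) paste(r$id, r$description) else r$id
        writeLines(paste0(">", hdr), con)
        s <- r$sequence
        starts <- seq(1L, nchar(s), by = width)
        writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a GenomeRecord
#'
#' @param strainId strain identifier.
#' @param contigs a [Biostrings::DNAStringSet], named character vector, or a
#'   list of records from [readFasta()].
#' @param currentGenus,currentSpecies current classification (species `"sp."`
#'   for strains unassigned at species level).
#' @param typeStrain logical; nomenclatural type strain of its species.
#' @param phylotype optional phylotype label.
#' @return a [GenomeRecord-class] object.
#' @export
genomeRecord <- function(strainId, contigs, currentGenus = NA_character_,
                         currentSpecies = NA_character_, typeStrain = FALSE,
                         phylotype = NA_character_) {
    if (is.list(contigs))
        contigs <- stats::setNames(
            vapply(contigs, `[[`, character(1), "sequence"),
            vapply(contigs, `[[`, character(1), "id"))
    if (!methods::is(contigs, "DNAStringSet"))
        contigs <- Biostrings::DNAStringSet(contigs)
    if (is.null(names(contigs)))
        names(contigs) <- paste0(strainId, "_contig", seq_along(contigs))
    methods::new("GenomeRecord", strainId = strainId, contigs = contigs,
        currentGenus = as.character(currentGenus),
        currentSpecies = as.character(currentSpecies),
        typeStrain = isTRUE(typeStrain),
        phylotype = as.character(phylotype))
}

#' Construct a ProteomeRecord
#'
#' @param strainId strain identifier.
#' @param proteins a [Biostrings::AAStringSet], named character vector, or a
#'   list of records from [readFasta()].
#' @return a [ProteomeRecord-class] object.
#' @export
proteomeRecord <- function(strainId, proteins) {
    if (is.list(proteins))
        proteins <- stats::setNames(
            vapply(proteins, `[[`, character(1), "sequence"),
            vapply(proteins, `[[`, character(1), "id"))
    if (!methods::is(proteins, "AAStringSet"))
        proteins <- Biostrings::AAStringSet(proteins)
    methods::new("ProteomeRecord", strainId = strainId, proteins = proteins)
}

#' Basic replicon statistics of a genome
#'
#' Total length counts every residue, ambiguity codes included. GC percent is
#' `100 * (G + C) / (A + C + G + T)`: ambiguity codes are excluded from both
#' numerator and denominator. With zero unambiguous bases the GC percent is
#' undefined (`NaN`) and a warning is raised.
#'
#' @param genome a [GenomeRecord-class].
#' @return `list(total_length, gc_percent, n_contigs)`.
#' @export
genomeStats <- function(genome) {
    stopifnot(methods::is(genome, "GenomeRecord"))
    af <- Biostrings::alphabetFrequency(genome@contigs)
    tot <- colSums(af)
    acgt <- sum(tot[c("A", "C", "G", "T")])
    gc <- if (acgt == 0) {
        warning("no unambiguous bases: GC percent undefined")
        NaN
    } else 100 * sum(tot[c("G", "C")]) / acgt
    list(total_length = sum(Biostrings::width(genome@contigs)),
         gc_percent = gc,
         n_contigs = length(genome@contigs))
}

#' Read a strain metadata table
#'
#' Tab-separated with header
#' `strain_id current_genus current_species type_strain phylotype`; returns
#' metadata-only [GenomeRecord-class] stubs (placeholder contig) keyed by
#' strain id. Duplicate strain ids are an error.
#'
#' @param path path to the TSV file.
#' @return named list of GenomeRecord stubs.
#' @export
readStrainMetadata <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
    need <- c("strain_id", "current_genus", "current_species",
              "type_strain", "phylotype")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("missing metadata columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(tab$strain_id))
        stop("duplicate strain ids: ",
             paste(unique(tab$strain_id[duplicated(tab$strain_id)]), collapse = ", "))
    recs <- lapply(seq_len(nrow(tab)), function(i) {
        genomeRecord(tab$strain_id[[i]], c(placeholder = "N"),
                     currentGenus = tab$current_genus[[i]],
                     currentSpecies = tab$current_species[[i]],
                     typeStrain = isTRUE(as.logical(tab$type_strain[[i]])),
                     phylotype = tab$phylotype[[i]])
    })
    stats::setNames(recs, tab$strain_id)
}

#' Square-matrix TSV round trip
#'
#' Writes/reads a square numeric matrix with strain ids as row and column
#' labels; the round trip preserves values and order.
#'
#' @param m numeric matrix with identical row and column names.
#' @param path file path.
#' @return `writeMatrixTSV`: `path` invisibly; `readMatrixTSV`: the matrix.
#' @export
writeMatrixTSV <- function(m, path) {
    stopifnot(is.matrix(m), identical(rownames(m), colnames(m)))
    df <- data.frame(strain_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    m
}

#' Newick tree input/output
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()]. Support
#' values travel as internal-node labels; the round trip preserves topology,
#' branch lengths (to 1e-9) and supports.
#'
#' @param tree an [ape::phylo] object.
#' @param path file path.
#' @return `readNewick`: a `phylo`; `writeNewick`: `path` invisibly.
#' @export
readNewick <- function(path) ape::read.tree(path)

#' @rdname readNewick
#' @export
writeNewick <- function(tree, path) {
    ape::write.tree(tree, file = path, digits = 12)
    invisible(path)
}
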