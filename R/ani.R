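#' ANI configuration
#'
#' Parameters of the fragment-based ANI computation. The defaults follow the
#' classic BLASTN-based protocol: non-overlapping 1,020-bp fragments, hits
#' kept when identity is at least 30 percent over at least 70 percent of the
#' fragment length. Alignment scoring is BLASTN-like (match +1, mismatch -2,
#' gap open -4, gap extend -2), seeded by exact 15-mers with banded
#' Smith-Waterman extension around seeded diagonals.
#'
#' @param fragment_length fragment size in bp (>= 100).
#' @param min_identity percent identity filter for fragment hits.
#' @param min_alignable minimum aligned fraction of the fragment.
#' @param seed_k exact-match seed length.
#' @param band half-width of the extension band around seeded diagonals.
#' @param match,mismatch,gap_open,gap_ext integer alignment scores.
#' @return a named list of parameters.
#' @export
aniConfig <- function(fragment_length = 1020L, min_identity = 30,
                      min_alignable = 0.70, seed_k = 15L, band = 32L,
                      match = 1L, mismatch = -2L, gap_open = 4L, gap_ext = 2L) {
    stopifnot(fragment_length >= 100)
    list(fragment_length = as.integer(fragment_length),
         min_identity = min_identity, min_alignable = min_alignable,
         seed_k = as.integer(seed_k), band = as.integer(band),
         match = as.integer(match), mismatch = as.integer(mismatch),
         gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext))
}

#' Cut a genome into consecutive non-overlapping fragments
#'
#' Fragments are taken per contig from position 0 in steps of
#' `fragment_length`; a trailing remainder shorter than the fragment length
#' is discarded, fragments never span contig boundaries, and fragments with
#' more than 50 percent ambiguous bases are dropped. Coordinates are 0-based,
#' half-open.
#'
#' @param genome a [GenomeRecord-class].
#' @param fragment_length fragment size in bp (default 1,020).
#' @return data.frame with columns `parent_contig`, `start`, `length`,
#'   `sequence`; zero rows (with a warning) when no contig yields a fragment.
#' @export
fragmentGenome <- function(genome, fragment_length = 1020L) {
    stopifnot(methods::is(genome, "GenomeRecord"), fragment_length >= 100)
    fragment_length <- as.integer(fragment_length)
    out <- list()
    for (i in seq_along(genome@contigs)) {
        L <- Biostrings::width(genome@contigs)[[i]]
        n <- L %/% fragment_length
        if (n == 0) next
        starts <- (seq_len(n) - 1L) * fragment_length
        seqs <- as.character(Biostrings::DNAStringSet(
            genome@contigs[[i]], start = starts + 1L, width = fragment_length))
        out[[length(out) + 1L]] <- data.frame(
            parent_contig = names(genome@contigs)[[i]],
            start = starts, length = fragment_length,
            sequence = toupper(unname(seqs)), stringsAsFactors = FALSE)
    }
    if (length(out) == 0) {
        warning("genome '", genome@strainId,
                "' is shorter than one fragment in every contig")
        return(data.frame(parent_contig = character(), start = integer(),
                          length = integer(), sequence = character(),
                          stringsAsFactors = FALSE))
    }
    frags <- do.call(rbind, out)
    ambig <- 1 - (nchar(gsub("[^ACGT]", "", frags$sequence)) / frags$length)
    frags <- frags[ambig <= 0.5, , drop = FALSE]
    rownames(frags) <- NULL
    frags
}

# internal: best hits for a set of fragment sequences against a genome
.fragmentHits <- function(fragment_seqs, reference, config) {
    refs <- toupper(as.character(reference@contigs))
    .fragment_hits_cpp(fragment_seqs, unname(refs),
                       config$min_identity, config$min_alignable,
                       config$seed_k, config$band,
                       config$match, config$mismatch,
                       config$gap_open, config$gap_ext)
}

#' Best local alignment of one fragment against a reference genome
#'
#' Finds the highest-scoring local alignment of the fragment against either
#' strand of the reference (exact 15-mer seeding, banded Smith-Waterman
#' extension; contigs searched separately). The hit is reported only if it
#' passes both the identity and the alignable-fraction filters. Identity is
#' matches over alignment columns, with gap columns counting as mismatches;
#' the alignable fraction is the fragment span covered by the alignment.
#'
#' @param fragment a single fragment sequence (character) or one row of
#'   [fragmentGenome()] output.
#' @param reference a [GenomeRecord-class] to search.
#' @param config an [aniConfig()] list.
#' @return `NULL` when no qualifying hit exists, otherwise
#'   `list(identity, alignable_fraction, strand, score, ref_contig)`.
#' @export
bestFragmentHit <- function(fragment, reference, config = aniConfig()) {
    if (is.data.frame(fragment)) fragment <- fragment$sequence[[1]]
    hit <- .fragmentHits(toupper(fragment), reference, config)
    if (!hit$found[[1]]) return(NULL)
    list(identity = hit$identity[[1]],
         alignable_fraction = hit$alignable_fraction[[1]],
         strand = hit$strand[[1]], score = hit$score[[1]],
         ref_contig = names(reference@contigs)[[hit$ref_contig[[1]]]])
}

#' Two-way average nucleotide identity between two genomes
#'
#' Each genome is virtually fragmented and its fragments aligned against the
#' other genome. One-way ANI is the unweighted mean identity of the
#' qualifying hits in that direction; the two-way value weights the two
#' directions by their hit counts (equivalently, the mean identity over all
#' qualifying hits of both directions). A self comparison returns 100.
#'
#' @param a,b [GenomeRecord-class] objects.
#' @param config an [aniConfig()] list.
#' @return `list(query_id, ref_id, ani_one_way_qr, ani_one_way_rq,
#'   ani_two_way, n_hits_qr, n_hits_rq, no_signal)`; when either direction
#'   has zero qualifying hits the ANI values are `NA` and `no_signal = TRUE`.
#' @export
twoWayANI <- function(a, b, config = aniConfig()) {
    fa <- fragmentGenome(a, config$fragment_length)
    fb <- fragmentGenome(b, config$fragment_length)
    hits_ab <- if (nrow(fa)) .fragmentHits(fa$sequence, b, config) else NULL
    hits_ba <- if (nrow(fb)) .fragmentHits(fb$sequence, a, config) else NULL
    id_ab <- if (is.null(hits_ab)) numeric() else hits_ab$identity[hits_ab$found]
    id_ba <- if (is.null(hits_ba)) numeric() else hits_ba$identity[hits_ba$found]
    n_ab <- length(id_ab); n_ba <- length(id_ba)
    no_signal <- n_ab == 0 || n_ba == 0
    list(query_id = a@strainId, ref_id = b@strainId,
         ani_one_way_qr = if (n_ab) mean(id_ab) else NA_real_,
         ani_one_way_rq = if (n_ba) mean(id_ba) else NA_real_,
         ani_two_way = if (no_signal) NA_real_ else
             (sum(id_ab) + sum(id_ba)) / (n_ab + n_ba),
         n_hits_qr = n_ab, n_hits_rq = n_ba, no_signal = no_signal)
}

#' All-vs-all ANI matrix for a panel of genomes
#'
#' Computes [twoWayANI()] for every unordered pair; the diagonal is set to
#' 100 and the symmetric two-way value is stored for both orientations.
#' No-signal pairs are recorded as `NA` with a message and are rejected by
#' the clustering stage rather than imputed.
#'
#' @param genomes list of [GenomeRecord-class] objects (>= 2).
#' @param config an [aniConfig()] list.
#' @return an [ANIMatrix-class].
#' @export
aniMatrix <- function(genomes, config = aniConfig()) {
    stopifnot(length(genomes) >= 2)
    ids <- vapply(genomes, strainId, character(1))
    if (anyDuplicated(ids)) stop("duplicate strain ids in panel")
    n <- length(genomes)
    m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    diag(m) <- 100
    for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
            res <- twoWayANI(genomes[[i]], genomes[[j]], config)
            if (res$no_signal)
                message("no ANI signal between ", ids[[i]], " and ", ids[[j]])
            m[i, j] <- m[j, i] <- res$ani_two_way
        }
    }
    methods::new("ANIMatrix", values = m)
}
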