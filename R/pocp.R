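#' @importFrom Biostrings pairwiseAlignment pid pattern nedit
NULL

.blosum62 <- function() {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
}

#' POCP configuration
#'
#' Filters and alignment parameters for the percentage-of-conserved-proteins
#' computation: a protein counts as conserved when its best BLASTP-style hit
#' in the partner proteome has E-value below `evalue_max`, identity of at
#' least `min_identity` percent, and covers at least `min_coverage` of the
#' query protein. Alignments use BLOSUM62 with affine gaps; E-values come
#' from the Karlin-Altschul formula `E = K * m * n * exp(-lambda * S)` with
#' search space = query length x total target residues.
#'
#' @param evalue_max E-value cut-off.
#' @param min_identity percent identity cut-off.
#' @param min_coverage minimum aligned fraction of the query protein.
#' @param gap_open,gap_ext affine gap penalties (positive costs).
#' @param K,lambda Karlin-Altschul constants for BLOSUM62.
#' @return a named parameter list.
#' @export
pocpConfig <- function(evalue_max = 1e-5, min_identity = 40, min_coverage = 0.5,
                       gap_open = 11, gap_ext = 1, K = 0.041, lambda = 0.267) {
    list(evalue_max = evalue_max, min_identity = min_identity,
         min_coverage = min_coverage, gap_open = gap_open, gap_ext = gap_ext,
         K = K, lambda = lambda)
}

#' Best protein hit of a query in a target proteome
#'
#' Highest-scoring Smith-Waterman alignment of the query against every
#' protein of the target proteome (BLOSUM62, affine gaps). Identity is
#' computed over alignment columns with gap columns counting as mismatches;
#' coverage is the aligned query span divided by the query length.
#'
#' @param query a single protein sequence (character) or a
#'   `list(id, sequence)` record.
#' @param target_proteome a [ProteomeRecord-class].
#' @param config a [pocpConfig()] list.
#' @return `list(target, score, identity, query_coverage, evalue)`, or `NULL`
#'   for an empty target proteome.
#' @export
proteinBestHit <- function(query, target_proteome, config = pocpConfig()) {
    if (is.list(query)) query <- query$sequence
    if (length(target_proteome@proteins) == 0) return(NULL)
    mat <- .blosum62()
    scores <- Biostrings::pairwiseAlignment(
        pattern = target_proteome@proteins, subject = Biostrings::AAString(query),
        type = "local", substitutionMatrix = mat,
        gapOpening = config$gap_open, gapExtension = config$gap_ext,
        scoreOnly = TRUE)
    best <- which.max(scores)
    al <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::AAString(query),
        subject = target_proteome@proteins[[best]],
        type = "local", substitutionMatrix = mat,
        gapOpening = config$gap_open, gapExtension = config$gap_ext)
    qlen <- nchar(query)
    tlen <- sum(Biostrings::width(target_proteome@proteins))
    s <- Biostrings::score(al)
    aligned_span <- Biostrings::end(Biostrings::pattern(al)) -
        Biostrings::start(Biostrings::pattern(al)) + 1L
    list(target = names(target_proteome@proteins)[[best]] %||% best,
         score = s,
         identity = Biostrings::pid(al, type = "PID1"),
         query_coverage = aligned_span / qlen,
         evalue = config$K * qlen * tlen * exp(-config$lambda * s))
}

# internal: logical vector, one per protein of `a`: conserved in `b`?
.conservedIn <- function(a, b, config) {
    vapply(seq_along(a@proteins), function(i) {
        hit <- proteinBestHit(as.character(a@proteins[[i]]), b, config)
        !is.null(hit) &&
            hit$evalue < config$evalue_max &&
            hit$identity >= config$min_identity &&
            hit$query_coverage >= config$min_coverage
    }, logical(1))
}

#' Percentage of conserved proteins between two proteomes
#'
#' `POCP = 100 * (C1 + C2) / (T1 + T2)` where `C1` counts proteins of `a`
#' with a qualifying best hit in `b` (and `C2` symmetrically), and `T1`,
#' `T2` are the proteome sizes. The coverage filter is applied per
#' direction, with the query being the proteome whose `C` is counted. The
#' result is symmetric in its arguments.
#'
#' @param a,b [ProteomeRecord-class] objects.
#' @param config a [pocpConfig()] list.
#' @return `list(id_a, id_b, C1, C2, T1, T2, pocp)`.
#' @export
pocpPair <- function(a, b, config = pocpConfig()) {
    C1 <- sum(.conservedIn(a, b, config))
    C2 <- sum(.conservedIn(b, a, config))
    T1 <- length(a@proteins); T2 <- length(b@proteins)
    list(id_a = a@strainId, id_b = b@strainId, C1 = C1, C2 = C2,
         T1 = T1, T2 = T2, pocp = 100 * (C1 + C2) / (T1 + T2))
}

#' Mean POCP of a strain against a group of proteomes
#'
#' Arithmetic mean of [pocpPair()] values over all group members; any group
#' member with the same strain id as the query (a self comparison) is
#' excluded.
#'
#' @param strain a [ProteomeRecord-class].
#' @param group non-empty list of [ProteomeRecord-class] objects.
#' @param config a [pocpConfig()] list.
#' @return mean POCP percent.
#' @export
meanPocpVsGroup <- function(strain, group, config = pocpConfig()) {
    group <- Filter(function(g) !identical(strainId(g), strainId(strain)), group)
    if (length(group) == 0) stop("empty comparison group")
    mean(vapply(group, function(g) pocpPair(strain, g, config)$pocp, numeric(1)))
}

#' Genus assignment from mean POCP values
#'
#' A strain is assigned to a genus when its mean POCP against that genus
#' reaches the threshold and stays below it for every other genus; at or
#' above the threshold for more than one genus the call is `"ambiguous"`
#' (genera listed in `genera_above`), below it everywhere `"neither"`.
#'
#' @param strain_id strain identifier.
#' @param mean_by_genus named numeric vector of mean POCP percent per genus.
#' @param threshold genus boundary in percent (default 60).
#' @return `list(strain_id, mean_pocp_by_genus, call, genera_above)`.
#' @export
genusCall <- function(strain_id, mean_by_genus, threshold = 60) {
    stopifnot(length(mean_by_genus) >= 1, !is.null(names(mean_by_genus)))
    above <- names(mean_by_genus)[mean_by_genus >= threshold]
    call <- if (length(above) == 1) above
            else if (length(above) == 0) "neither"
            else "ambiguous"
    list(strain_id = strain_id, mean_pocp_by_genus = mean_by_genus,
         call = call, genera_above = above)
}
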