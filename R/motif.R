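IUPAC_SETS <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

# "(A/T)" alternative notation -> IUPAC one-letter class
.normalizeConsensus <- function(consensus) {
    s <- toupper(gsub("\\s", "", consensus))
    while (grepl("\\(", s)) {
        grp <- regmatches(s, regexpr("\\(([ACGT]/)+[ACGT]\\)", s))
        if (!length(grp)) stop("unparseable consensus group in: ", consensus)
        bases <- sort(unique(strsplit(gsub("[()/]", "", grp), "")[[1]]))
        code <- names(Filter(function(set) identical(sort(set), bases), IUPAC_SETS))
        if (!length(code)) stop("no IUPAC code for base set: ",
                                paste(bases, collapse = "/"))
        s <- sub(grp, code[[1]], s, fixed = TRUE)
    }
    s
}

#' Define a degenerate consensus motif
#'
#' @param name motif name.
#' @param consensus consensus over IUPAC nucleotide codes; `(A/T)`-style
#'   alternative groups are normalised to the corresponding IUPAC letter.
#' @param max_mismatches mismatch tolerance for [scanMotif()].
#' @param search_both_strands scan the reverse strand too (default TRUE).
#' @return `list(name, consensus, max_mismatches, search_both_strands)`.
#' @export
motifPattern <- function(name, consensus, max_mismatches = 0L,
                         search_both_strands = TRUE) {
    consensus <- .normalizeConsensus(consensus)
    if (nchar(consensus) < 4) stop("consensus must be at least 4 long")
    bad <- setdiff(unique(strsplit(consensus, "")[[1]]), names(IUPAC_SETS))
    if (length(bad)) stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "))
    list(name = name, consensus = consensus,
         max_mismatches = as.integer(max_mismatches),
         search_both_strands = isTRUE(search_both_strands))
}

#' Replication-motif consensus patterns
#'
#' The three built-in replication signals: the chromosomal DnaA box
#' `TTWTNCACA` (tolerating one mismatch), the RepA-binding iteron
#' `CGCWGAWWYVGGTWCGS` and the TrfA-binding iteron `VHGCCCCYCAWGTGTCA`
#' (each tolerating two mismatches by default; the iteron allowances are
#' package defaults, configurable through [motifPattern()]).
#'
#' @return a named list of [motifPattern()] objects.
#' @export
builtinMotifPatterns <- function() {
    list(dnaA_box = motifPattern("dnaA_box", "TT(A/T)TNCACA", 1L),
         repA_iteron = motifPattern(
             "repA_iteron", "CGC(A/T)GA(A/T)(A/T)(C/T)(A/C/G)GGT(A/T)CG(C/G)", 2L),
         trfA_iteron = motifPattern(
             "trfA_iteron", "(A/C/G)(A/C/T)GCCCC(C/T)CA(A/T)GTGTCA", 2L))
}

# mismatch count per window start for one oriented pattern on one sequence.
# A genome base matches a pattern class when it is an unambiguous base in the
# class's set, or is literally identical to the class letter -- so N in the
# genome never matches a non-N class.
.windowMismatches <- function(seq_chars, pattern_chars) {
    L <- length(pattern_chars)
    n <- length(seq_chars) - L + 1L
    if (n < 1) return(integer(0))
    mism <- integer(n)
    for (k in seq_len(L)) {
        cls <- pattern_chars[[k]]
        win <- seq_chars[k:(k + n - 1L)]
        ok <- win %in% IUPAC_SETS[[cls]] | win == cls
        mism <- mism + !ok
    }
    mism
}

#' Scan a genome for degenerate motif occurrences
#'
#' Reports every window (on both strands when enabled) whose number of
#' positions violating the pattern's IUPAC class is at most the pattern's
#' mismatch allowance. Coordinates are 0-based half-open on the forward
#' strand; the matched sequence is reported in the orientation of the hit
#' strand. Overlapping hits are all reported; the list is sorted by
#' (contig, start, strand).
#'
#' @param genome a [GenomeRecord-class].
#' @param pattern a [motifPattern()] object.
#' @return data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `mismatches`, `matched`.
#' @export
scanMotif <- function(genome, pattern) {
    stopifnot(methods::is(genome, "GenomeRecord"))
    pat <- strsplit(pattern$consensus, "")[[1]]
    L <- length(pat)
    rc_pat <- rev(unname(IUPAC_COMPLEMENT[pat]))
    out <- list()
    for (i in seq_along(genome@contigs)) {
        cname <- names(genome@contigs)[[i]]
        s <- strsplit(toupper(as.character(genome@contigs[[i]])), "")[[1]]
        strands <- if (pattern$search_both_strands) c("+", "-") else "+"
        for (st in strands) {
            p <- if (st == "+") pat else rc_pat
            mism <- .windowMismatches(s, p)
            hit <- which(mism <= pattern$max_mismatches)
            if (!length(hit)) next
            matched <- vapply(hit, function(h)
                paste0(s[h:(h + L - 1L)], collapse = ""), character(1))
            if (st == "-")
                matched <- vapply(strsplit(matched, ""), function(ch)
                    paste0(rev(unname(IUPAC_COMPLEMENT[ch])), collapse = ""),
                    character(1))
            out[[length(out) + 1L]] <- data.frame(
                contig = cname, start = hit - 1L, end = hit - 1L + L,
                strand = st, mismatches = mism[hit], matched = matched,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(contig = character(), start = integer(),
                          end = integer(), strand = character(),
                          mismatches = integer(), matched = character(),
                          stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    res <- res[order(match(res$contig, names(genome@contigs)),
                     res$start, res$strand), ]
    rownames(res) <- NULL
    res
}
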