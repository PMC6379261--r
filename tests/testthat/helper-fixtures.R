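# Shared helpers: tiny fixtures and independent brute-force oracles.

rc <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

write_tmp_fasta <- function(text) {
    f <- tempfile(fileext = ".fasta")
    writeLines(text, f)
    f
}

# Independent Smith-Waterman oracle for nucleotide fragments: exhaustive
# local alignment via Biostrings under the package's BLASTN-like scoring,
# checked on both strands.
sw_oracle <- function(fragment, ref_seq) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(1, -2, baseOnly = TRUE)
    best <- list(score = -Inf)
    for (strand in c("+", "-")) {
        q <- if (strand == "+") fragment else rc(fragment)
        al <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(q), Biostrings::DNAString(ref_seq),
            type = "local", substitutionMatrix = mat,
            gapOpening = 4, gapExtension = 2)
        if (Biostrings::score(al) > best$score)
            best <- list(score = Biostrings::score(al),
                         identity = Biostrings::pid(al, type = "PID1"),
                         strand = strand)
    }
    best
}

# Independent per-window brute-force motif oracle (plain R loops, no shared
# machinery with scanMotif beyond the IUPAC tables).
motif_oracle <- function(seq_string, consensus, max_mm, both_strands = TRUE) {
    iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                  Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                  D = c("A", "G", "T"), H = c("A", "C", "T"),
                  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
              W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
              N = "N")
    s <- strsplit(toupper(seq_string), "")[[1]]
    pats <- list("+" = strsplit(consensus, "")[[1]])
    if (both_strands)
        pats[["-"]] <- rev(unname(comp[pats[["+"]]]))
    L <- nchar(consensus)
    out <- NULL
    for (st in names(pats)) {
        p <- pats[[st]]
        for (i in seq_len(length(s) - L + 1)) {
            mm <- 0L
            for (k in seq_len(L)) {
                ch <- s[i + k - 1]
                ok <- (ch %in% iupac[[p[k]]]) || ch == p[k]
                if (!ok) mm <- mm + 1L
            }
            if (mm <= max_mm)
                out <- rbind(out, data.frame(start = i - 1L, strand = st,
                                             mismatches = mm))
        }
    }
    out
}

# Exact two-sided Fisher p by exhaustive hypergeometric enumeration with
# fixed margins (minimum-likelihood rule).
fisher_oracle <- function(a, b, c, d) {
    m1 <- a + b; m2 <- c + d; n1 <- a + c
    lo <- max(0, n1 - m2); hi <- min(n1, m1)
    probs <- vapply(lo:hi, function(x)
        choose(m1, x) * choose(m2, n1 - x) / choose(m1 + m2, n1), numeric(1))
    obs <- probs[a - lo + 1]
    sum(probs[probs <= obs * (1 + 1e-7)])
}

# Small deterministic marker alignment fixture evolved on a known tree.
make_marker_fixture <- function(n_taxa = 6, len = 600, seed = 42) {
    tr <- withSeed(seed, ape::rcoal(n_taxa))
    tr$edge.length <- tr$edge.length * 0.3 / max(ape::node.depth.edgelength(tr))
    aln <- generateMarkers(tr, c(gene = len), seed = seed)$gene
    list(tree = tr, aln = aln)
}
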