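#' Synthetic genome ancestor
#'
#' i.i.d. bases with `P(G or C) = gc` (split evenly between G and C, and
#' between A and T). Bit-reproducible for a given seed.
#'
#' @param length genome length in bp (>= 4).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @param strain_id id for the returned record.
#' @return a single-contig [GenomeRecord-class].
#' @export
generateAncestor <- function(length, gc = 0.5, seed = 1L,
                             strain_id = "ancestor") {
    stopifnot(length >= 4, gc >= 0, gc <= 1)
    seq <- withSeed(seed, paste0(
        sample(c("A", "T", "G", "C"), length, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = ""))
    genomeRecord(strain_id, stats::setNames(seq, paste0(strain_id, "_c1")))
}

.mutateSeq <- function(chars, rate) {
    if (rate <= 0) return(chars)
    hit <- which(stats::runif(length(chars)) < rate)
    if (length(hit)) {
        alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T",
                        "A", "C", "G"), nrow = 3)
        colnames(alt) <- c("A", "C", "G", "T")
        pick <- sample.int(3L, length(hit), replace = TRUE)
        chars[hit] <- alt[cbind(pick, match(chars[hit], colnames(alt)))]
    }
    chars
}

#' Evolve a genome by substitutions and indels
#'
#' Each site is substituted with the given per-site probability, uniformly
#' among the three alternative bases, so the expected ungapped identity to
#' the parent is `1 - substitution_rate`. Indel events occur per site with
#' probability `indel_rate` (insertion or deletion with equal probability)
#' and geometric lengths with the given mean. Indels default to off so that
#' the expected identity stays analytic.
#'
#' @param genome a [GenomeRecord-class].
#' @param substitution_rate per-site substitution probability in `[0, 1)`.
#' @param indel_rate per-site indel event probability in `[0, 1)`.
#' @param mean_indel_length mean indel length in bp.
#' @param seed RNG seed.
#' @param strain_id id of the evolved record.
#' @return a [GenomeRecord-class] with the same contig structure.
#' @export
evolveGenome <- function(genome, substitution_rate, indel_rate = 0,
                         mean_indel_length = 3, seed = 1L,
                         strain_id = paste0(strainId(genome), "_evolved")) {
    stopifnot(substitution_rate >= 0, substitution_rate < 1,
              indel_rate >= 0, indel_rate < 1)
    seqs <- withSeed(seed, lapply(as.character(genome@contigs), function(s) {
        chars <- .mutateSeq(strsplit(toupper(s), "")[[1]], substitution_rate)
        if (indel_rate > 0) {
            n_events <- stats::rbinom(1, length(chars), indel_rate)
            for (e in seq_len(n_events)) {
                pos <- sample.int(length(chars), 1)
                len <- stats::rgeom(1, 1 / mean_indel_length) + 1L
                if (stats::runif(1) < 0.5) {
                    ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
                    chars <- append(chars, ins, after = pos)
                } else {
                    drop <- pos:min(pos + len - 1L, length(chars))
                    if (length(drop) < length(chars)) chars <- chars[-drop]
                }
            }
        }
        paste0(chars, collapse = "")
    }))
    genomeRecord(strain_id, stats::setNames(unlist(seqs),
        paste0(strain_id, "_c", seq_along(seqs))),
        currentGenus = genome@currentGenus,
        currentSpecies = genome@currentSpecies)
}

# identity -> JC branch length, and JC branch -> per-site change probability
.jcDist <- function(identity) -0.75 * log(1 - 4 * (1 - identity) / 3)
.jcProb <- function(branch) 0.75 * (1 - exp(-4 * branch / 3))

#' Generate a strain panel with planted clade structure
#'
#' Simulates `n_per_clade` strains in each of several clades descending
#' from a common ancestor, calibrated (through Jukes-Cantor additivity) so
#' that the expected pairwise sequence identity is `within_identity` inside
#' a clade and `between_identity` across clades. The planted clade labels
#' are returned alongside the genomes; designs with
#' `within_identity <= between_identity` are rejected.
#'
#' @param n_per_clade integer vector, strains per clade.
#' @param within_identity,between_identity expected pairwise identities in
#'   `(0, 1]`.
#' @param genome_length ancestor length in bp.
#' @param gc ancestor GC fraction.
#' @param seed RNG seed.
#' @return `list(genomes, truth)`: a list of [GenomeRecord-class] and a
#'   named character vector of planted clade labels.
#' @export
generatePanel <- function(n_per_clade = c(3, 3), within_identity = 0.97,
                          between_identity = 0.85, genome_length = 50000L,
                          gc = 0.6, seed = 1L) {
    if (within_identity <= between_identity)
        stop("infeasible design: within-identity must exceed between-identity")
    branch_w <- .jcDist(within_identity) / 2
    branch_b <- .jcDist(between_identity) / 2 - branch_w
    if (branch_b < 0) stop("infeasible design: between-clade divergence too small")
    root <- generateAncestor(genome_length, gc, seed, "root")
    genomes <- list(); truth <- character()
    for (cl in seq_along(n_per_clade)) {
        anc <- evolveGenome(root, .jcProb(branch_b), seed = seed + 1000L * cl,
                            strain_id = paste0("clade", cl))
        for (k in seq_len(n_per_clade[[cl]])) {
            id <- paste0("clade", cl, "_s", k)
            g <- evolveGenome(anc, .jcProb(branch_w),
                              seed = seed + 1000L * cl + k, strain_id = id)
            genomes[[id]] <- g
            truth[[id]] <- paste0("clade", cl)
        }
    }
    list(genomes = genomes, truth = truth)
}

.randomProtein <- function(len) {
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    paste0(sample(aas, len, replace = TRUE), collapse = "")
}

.mutateProtein <- function(seq, rate) {
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    chars <- strsplit(seq, "")[[1]]
    hit <- which(stats::runif(length(chars)) < rate)
    for (h in hit) chars[[h]] <- sample(setdiff(aas, chars[[h]]), 1)
    paste0(chars, collapse = "")
}

#' Generate a proteome pair with a planted shared-ortholog fraction
#'
#' A fraction `shared_fraction` of the proteins are near-identical ortholog
#' pairs (per-residue divergence `divergence`); the remainder of each
#' proteome is strain-specific random protein. The planted POCP equals
#' `100 * shared_fraction`.
#'
#' @param n_proteins proteins per proteome.
#' @param shared_fraction fraction of shared orthologs in `[0, 1]`.
#' @param divergence per-residue substitution probability of ortholog pairs.
#' @param length_range min/max protein length.
#' @param seed RNG seed.
#' @return `list(a, b, planted_pocp)` with two [ProteomeRecord-class]s.
#' @export
generateProteomePair <- function(n_proteins = 40L, shared_fraction = 0.6,
                                 divergence = 0.05,
                                 length_range = c(120L, 300L), seed = 1L) {
    stopifnot(shared_fraction >= 0, shared_fraction <= 1)
    n_shared <- round(n_proteins * shared_fraction)
    withSeed(seed, {
        lens <- sample(length_range[1]:length_range[2], n_proteins,
                       replace = TRUE)
        pa <- pb <- character(n_proteins)
        for (i in seq_len(n_proteins)) {
            if (i <= n_shared) {
                pa[[i]] <- .randomProtein(lens[[i]])
                pb[[i]] <- .mutateProtein(pa[[i]], divergence)
            } else {
                pa[[i]] <- .randomProtein(lens[[i]])
                pb[[i]] <- .randomProtein(sample(
                    length_range[1]:length_range[2], 1))
            }
        }
        list(a = proteomeRecord("sim_a",
                 stats::setNames(pa, paste0("a_", seq_len(n_proteins)))),
             b = proteomeRecord("sim_b",
                 stats::setNames(pb, paste0("b_", seq_len(n_proteins)))),
             planted_pocp = 100 * n_shared / n_proteins)
    })
}

#' Evolve marker-gene alignments along a known tree
#'
#' Simulates one gapless alignment per gene by evolving i.i.d. root
#' sequences site-wise under the Jukes-Cantor model along the branches of
#' the given tree, so the generating tree is the ground truth for
#' tree-recovery tests.
#'
#' @param tree an [ape::phylo] with branch lengths (expected substitutions
#'   per site).
#' @param gene_lengths named integer vector of alignment lengths per gene.
#' @param seed RNG seed.
#' @return named list of alignments (named character vectors).
#' @export
generateMarkers <- function(tree, gene_lengths, seed = 1L) {
    stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
    bases <- c("A", "C", "G", "T")
    withSeed(seed, lapply(stats::setNames(gene_lengths,
                                          names(gene_lengths)), function(L) {
        n_nodes <- max(tree$edge)
        seqs <- vector("list", n_nodes)
        root <- length(tree$tip.label) + 1L
        seqs[[root]] <- sample(bases, L, replace = TRUE)
        for (e in seq_len(nrow(tree$edge))) {  # ape edges are preorder
            from <- tree$edge[e, 1]; to <- tree$edge[e, 2]
            p <- .jcProb(tree$edge.length[[e]])
            child <- seqs[[from]]
            hit <- which(stats::runif(L) < p)
            if (length(hit))
                child[hit] <- vapply(child[hit], function(b)
                    sample(setdiff(bases, b), 1), character(1))
            seqs[[to]] <- child
        }
        stats::setNames(vapply(seq_along(tree$tip.label), function(i)
            paste0(seqs[[i]], collapse = ""), character(1)), tree$tip.label)
    }))
}

#' Plant motif occurrences into a genome
#'
#' Writes one realisation of the consensus (a uniform draw within each
#' IUPAC class) at each requested position, optionally perturbed by
#' per-site noise, and returns the modified genome together with the truth
#' table of planted coordinates.
#'
#' @param genome a [GenomeRecord-class].
#' @param pattern a [motifPattern()] object.
#' @param positions data.frame with columns `contig`, `start` (0-based) and
#'   `strand` (`"+"`/`"-"`).
#' @param noise per-site probability of substituting a planted base.
#' @param seed RNG seed.
#' @return `list(genome, truth)`.
#' @export
plantMotifs <- function(genome, pattern, positions, noise = 0, seed = 1L) {
    pat <- strsplit(pattern$consensus, "")[[1]]
    seqs <- lapply(as.character(genome@contigs), function(s)
        strsplit(toupper(s), "")[[1]])
    names(seqs) <- names(genome@contigs)
    withSeed(seed, {
        for (r in seq_len(nrow(positions))) {
            site <- vapply(pat, function(cls)
                sample(IUPAC_SETS[[cls]], 1), character(1))
            if (noise > 0) site <- .mutateSeq(site, noise)
            if (positions$strand[[r]] == "-")
                site <- rev(unname(IUPAC_COMPLEMENT[site]))
            ctg <- positions$contig[[r]]; st <- positions$start[[r]]
            stopifnot(st + length(pat) <= length(seqs[[ctg]]))
            seqs[[ctg]][(st + 1):(st + length(pat))] <- site
        }
    })
    g <- genomeRecord(strainId(genome),
        stats::setNames(vapply(seqs, paste0, character(1), collapse = ""),
                        names(seqs)))
    list(genome = g, truth = positions)
}
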