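test_that("gap-column elimination is complete, idempotent and oracle-exact", {
    expect_equal(removeGapColumns(c(x = "A-C", y = "AGC")),
                 c(x = "AC", y = "AC"))
    gapless <- c(x = "ACGT", y = "TGCA")
    expect_equal(removeGapColumns(gapless), gapless)
    expect_error(removeGapColumns(c(x = "-N", y = "A-")), "no columns")

    aln <- withSeed(301, {
        chars <- c("A", "C", "G", "T", "-", "N")
        vapply(1:10, function(i) paste0(
            sample(chars, 80, TRUE, prob = c(rep(0.22, 4), 0.06, 0.06)),
            collapse = ""), character(1))
    })
    names(aln) <- paste0("s", 1:10)
    filtered <- removeGapColumns(aln)
    # brute-force column scan oracle
    m <- do.call(rbind, strsplit(aln, ""))
    keep <- colSums(m == "-" | m == "." | m == "N" | m == "X") == 0
    expect_equal(unique(nchar(filtered)), sum(keep))
    expect_equal(removeGapColumns(filtered), filtered)
})

test_that("marker concatenation preserves order, lengths and strain sets", {
    strains <- paste0("s", 1:4)
    lens <- c(atpD = 1278, leuS = 2571, rplB = 822, gyrB = 1662)
    alns <- withSeed(302, lapply(lens, function(L)
        stats::setNames(vapply(strains, function(s) paste0(
            sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
            character(1)), strains)))
    cc <- concatenateAlignments(alns)
    expect_equal(cc$total_length, 6333)
    expect_equal(unname(cc$gene_lengths), unname(lens))
    expect_equal(cc$gene_order, names(lens))

    single <- concatenateAlignments(alns["atpD"])
    expect_equal(single$rows, alns$atpD)

    # permuting strain insertion order of one gene leaves the rows unchanged
    perm <- alns
    perm$leuS <- perm$leuS[c(3, 1, 4, 2)]
    expect_equal(concatenateAlignments(perm)$rows[strains], cc$rows[strains])

    bad <- alns
    names(bad$gyrB)[1] <- "intruder"
    expect_error(concatenateAlignments(bad), "intruder")
})

test_that("percent identity uses pairwise comparable columns only", {
    expect_equal(percentIdentity("ACGT", "ACGT"), 100)
    expect_equal(percentIdentity("ACGT", "ACGA"), 75)
    # gap and ambiguity columns dropped pairwise
    expect_equal(percentIdentity("AC-GTN", "ACTGTA"), 100)
    expect_warning(p <- percentIdentity("--", "AA"), "comparable")
    expect_true(is.na(p))
})

test_that("distances follow the p and JC69 models", {
    aln <- c(a = strrep("A", 100), b = strrep("A", 100), c = strrep("A", 100))
    d0 <- distanceMatrix(aln, "p-distance")
    expect_true(all(d0$values == 0))

    # p = 0.10 -> JC69 = 0.10732...
    b <- paste0(strrep("C", 10), strrep("A", 90))
    aln2 <- c(a = strrep("A", 100), b = b,
              c = paste0("G", strrep("A", 99)))
    dp <- distanceMatrix(aln2, "p-distance")
    expect_equal(dp$values["a", "b"], 0.10)
    dj <- distanceMatrix(aln2, "JC69")
    expect_equal(dj$values["a", "b"], -0.75 * log(1 - 0.4 / 3),
                 tolerance = 1e-9)
    expect_equal(dj$values, t(dj$values))
    expect_true(all(diag(dj$values) == 0))

    far <- c(a = strrep("A", 20), b = strrep("C", 20), c = strrep("G", 20))
    expect_error(distanceMatrix(far, "JC69"), "a / b")
})

test_that("NJ solves the three-taxon case in closed form", {
    d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
    tr <- njTree(d)
    len <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                           tr$tip.label)
    expect_equal(len[["a"]], 1)
    expect_equal(len[["b"]], 1)
    expect_equal(len[["c"]], 3)
})

test_that("NJ reproduces additive four-taxon trees exactly", {
    # tree ((A:1,B:2):1.5,(C:3,D:1)); additive path distances
    d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    d["A", "B"] <- d["B", "A"] <- 3
    d["A", "C"] <- d["C", "A"] <- 5.5
    d["A", "D"] <- d["D", "A"] <- 3.5
    d["B", "C"] <- d["C", "B"] <- 6.5
    d["B", "D"] <- d["D", "B"] <- 4.5
    d["C", "D"] <- d["D", "C"] <- 4
    tr <- njTree(d)
    pd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    expect_equal(pd, d, tolerance = 1e-6)
    # AB|CD split present
    splits <- ape::prop.part(tr)
    expect_true(any(vapply(splits, function(s)
        setequal(tr$tip.label[s], c("A", "B")) ||
        setequal(tr$tip.label[s], c("C", "D")), logical(1))))
})

test_that("UPGMA trees are ultrametric and recover clock-like topologies", {
    fix <- make_marker_fixture(n_taxa = 6, len = 1200, seed = 303)
    d <- distanceMatrix(fix$aln, "JC69")
    tr <- upgmaTree(d)
    depths <- ape::node.depth.edgelength(tr)
    tip_depths <- depths[seq_along(tr$tip.label)]
    expect_lt(diff(range(tip_depths)), 1e-9)
    # topology matches the generating coalescent tree
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(fix$tree))[[1]], 0)
})

test_that("bootstrap supports are deterministic, bounded and converge", {
    blocks <- withSeed(304, {
        base <- replicate(4, paste0(sample(c("A", "C", "G", "T"), 400, TRUE),
                                    collapse = ""))
        stats::setNames(base, paste0("t", 1:4))
    })
    # four highly divergent, internally congruent sequences
    tr1 <- bootstrapSupport(blocks, "nj", n_replicates = 200, seed = 99)
    tr2 <- bootstrapSupport(blocks, "nj", n_replicates = 200, seed = 99)
    expect_identical(tr1$node.label, tr2$node.label)
    expect_true(all(tr1$node.label >= 0 & tr1$node.label <= 100))

    fix <- make_marker_fixture(n_taxa = 6, len = 900, seed = 305)
    t100 <- bootstrapSupport(fix$aln, "nj", n_replicates = 100, seed = 1)
    t1000 <- bootstrapSupport(fix$aln, "nj", n_replicates = 1000, seed = 1)
    expect_true(all(abs(t100$node.label - t1000$node.label) <= 5))
})
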