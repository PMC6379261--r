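make_proteome <- function(id, seqs) {
    proteomeRecord(id, stats::setNames(seqs, paste0(id, "_", seq_along(seqs))))
}

random_protein <- function(len) {
    paste0(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, TRUE),
           collapse = "")
}

test_that("protein best hits report identity, coverage and E-value", {
    withSeed(101, {
        q <- random_protein(200)
        target <- make_proteome("t", c(q, random_protein(150)))
        hit <- proteinBestHit(q, target)
        expect_equal(hit$identity, 100)
        expect_equal(hit$query_coverage, 1.0)
        expect_lt(hit$evalue, 1e-5)

        # target holding only the first half of the query forces ~50% coverage
        half <- make_proteome("h", substr(q, 1, 100))
        hhit <- proteinBestHit(q, half)
        expect_equal(hhit$query_coverage, 0.5, tolerance = 0.03)
        expect_lte(hhit$query_coverage, 0.51)
    })
})

test_that("shuffled decoys rarely reach the E-value cut-off", {
    hits <- withSeed(103, vapply(1:100, function(i) {
        q <- random_protein(200)
        decoys <- vapply(1:5, function(j)
            paste0(sample(strsplit(q, "")[[1]]), collapse = ""), character(1))
        proteinBestHit(q, make_proteome("d", decoys))$evalue
    }, numeric(1)))
    expect_gte(sum(hits > 1e-5), 95)
})

test_that("POCP is symmetric, 100 on self, and forced by its formula", {
    pp <- generateProteomePair(n_proteins = 30, shared_fraction = 0.5,
                               divergence = 0.05, seed = 111)
    self <- pocpPair(pp$a, pp$a)
    expect_equal(self$pocp, 100)

    ab <- pocpPair(pp$a, pp$b)
    ba <- pocpPair(pp$b, pp$a)
    expect_equal(ab$pocp, ba$pocp)
    expect_equal(ab$C1, ba$C2)

    # constructed fixture forcing C1 = 3, C2 = 4, T1 = T2 = 10 -> 35.0
    withSeed(112, {
        shared <- vapply(1:3, function(i) random_protein(180), character(1))
        a <- make_proteome("a", c(shared, vapply(1:7, function(i)
            random_protein(160), character(1))))
        b <- make_proteome("b", c(shared, shared[1], vapply(1:6, function(i)
            random_protein(160), character(1))))
        r <- pocpPair(a, b)
        expect_equal(r$C1, 3)
        expect_equal(r$C2, 4)
        expect_equal(r$T1, 10)
        expect_equal(r$T2, 10)
        expect_equal(r$pocp, 35.0)

        # dropping one conserved protein from a: C1 and T1 both fall by 1
        a2 <- make_proteome("a2", as.character(proteins(a))[-1])
        r2 <- pocpPair(a2, b)
        expect_equal(r2$C1, r$C1 - 1)
        expect_equal(r2$T1, r$T1 - 1)
    })
})

test_that("planted shared-ortholog fractions are recovered within 3 points", {
    for (f in c(0.2, 0.5, 0.8)) {
        pp <- generateProteomePair(n_proteins = 40, shared_fraction = f,
                                   divergence = 0.05, seed = 120 + f * 10)
        r <- pocpPair(pp$a, pp$b)
        expect_equal(r$pocp, pp$planted_pocp, tolerance = 3 / pp$planted_pocp)
    }
})

test_that("group means exclude self and average planted levels", {
    pp_hi <- generateProteomePair(n_proteins = 30, shared_fraction = 0.8,
                                  divergence = 0.03, seed = 131)
    pp_lo <- generateProteomePair(n_proteins = 30, shared_fraction = 0.4,
                                  divergence = 0.03, seed = 132)
    strain <- pp_hi$a
    # group of exact copies of the strain itself (under other ids) -> 100
    copies <- list(proteomeRecord("c1", proteins(strain)),
                   proteomeRecord("c2", proteins(strain)))
    expect_equal(meanPocpVsGroup(strain, copies), 100)
    # self excluded; empty-after-exclusion errors
    expect_error(meanPocpVsGroup(strain, list(strain)), "empty")

    hi <- pocpPair(pp_hi$a, pp_hi$b)$pocp
    lo2 <- generateProteomePair(n_proteins = 30, shared_fraction = 0.4,
                                divergence = 0.03, seed = 133)
    m <- meanPocpVsGroup(pp_hi$a, list(pp_hi$b, pp_lo$b))
    expect_equal(m, mean(c(hi, pocpPair(pp_hi$a, pp_lo$b)$pocp)))
})

test_that("genus calls apply the 60% boundary rule", {
    expect_equal(genusCall("s", c(Cupriavidus = 70, Ralstonia = 55))$call,
                 "Cupriavidus")
    pba <- genusCall("PBA", c(Cupriavidus = 51.4, Ralstonia = 52.6))
    expect_equal(pba$call, "neither")
    amb <- genusCall("s", c(Cupriavidus = 65, Ralstonia = 65))
    expect_equal(amb$call, "ambiguous")
    expect_setequal(amb$genera_above, c("Cupriavidus", "Ralstonia"))
})
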