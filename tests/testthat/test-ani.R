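test_that("fragmentation follows the non-overlapping window rules", {
    g <- generateAncestor(5100, 0.5, seed = 1, strain_id = "g")
    fr <- fragmentGenome(g, 1020)
    expect_equal(nrow(fr), 5)
    expect_equal(fr$start, c(0, 1020, 2040, 3060, 4080))
    expect_true(all(fr$length == 1020))

    short <- genomeRecord("s", c(c1 = strrep("ACGT", 250)))  # 1000 bp
    expect_warning(fr0 <- fragmentGenome(short, 1020), "shorter")
    expect_equal(nrow(fr0), 0)

    two <- genomeRecord("t", c(
        c1 = substr(as.character(contigs(g)[[1]]), 1, 2040),
        c2 = substr(as.character(contigs(g)[[1]]), 1, 1530)))
    expect_equal(nrow(fragmentGenome(two, 1020)), 3)

    # a fragment-sized window that is mostly N is discarded
    s <- as.character(contigs(g)[[1]])
    substr(s, 1, 600) <- strrep("N", 600)
    gn <- genomeRecord("n", c(c1 = s))
    expect_equal(nrow(fragmentGenome(gn, 1020)), 4)
})

test_that("best fragment hits match the exhaustive Smith-Waterman oracle", {
    ref <- generateAncestor(12000, 0.55, seed = 21, strain_id = "ref")
    ref_seq <- as.character(contigs(ref)[[1]])

    # verbatim fragment
    frag <- substr(ref_seq, 3001, 4020)
    hit <- bestFragmentHit(frag, ref)
    expect_equal(hit$identity, 100)
    expect_equal(hit$alignable_fraction, 1.0)
    expect_equal(hit$strand, "+")

    # reverse-complemented fragment: same identity, minus strand, and the
    # oracle agrees on both score and identity
    hit_rc <- bestFragmentHit(rc(frag), ref)
    expect_equal(hit_rc$identity, 100)
    expect_equal(hit_rc$strand, "-")
    orc <- sw_oracle(rc(frag), ref_seq)
    expect_equal(hit_rc$score, orc$score)
    expect_equal(hit_rc$identity, orc$identity, tolerance = 1e-6)

    # mutated fragments: per-fragment best hit equals the full SW optimum
    mut <- evolveGenome(ref, 0.08, seed = 22, strain_id = "mut")
    mut_seq <- as.character(contigs(mut)[[1]])
    for (i in 0:5) {
        f <- substr(mut_seq, i * 1500 + 1, i * 1500 + 1020)
        h <- bestFragmentHit(f, ref)
        o <- sw_oracle(f, ref_seq)
        expect_equal(h$score, o$score)
        expect_equal(h$identity, o$identity, tolerance = 1e-6)
        expect_equal(h$strand, o$strand)
    }
})

test_that("unrelated random fragments never yield qualifying hits", {
    ref <- generateAncestor(100000, 0.5, seed = 31, strain_id = "bigref")
    frags <- withSeed(32, vapply(1:100, function(i)
        paste0(sample(c("A", "C", "G", "T"), 1020, TRUE), collapse = ""),
        character(1)))
    hits <- taxongauge:::.fragmentHits(frags, ref, aniConfig())
    expect_false(any(hits$found))
})

test_that("two-way ANI is exact on self and calibrated on mutated copies", {
    g <- generateAncestor(30000, 0.6, seed = 41, strain_id = "g")
    self <- twoWayANI(g, g)
    expect_equal(self$ani_two_way, 100)
    expect_equal(self$n_hits_qr, nrow(fragmentGenome(g)))

    # a copy mutated at rate 0.05 has expected identity 95%; use a genome
    # long enough for >= 100 fragments
    big <- generateAncestor(110000, 0.6, seed = 42, strain_id = "big")
    mut <- evolveGenome(big, 0.05, seed = 43, strain_id = "mut")
    res <- twoWayANI(big, mut)
    expect_gte(res$n_hits_qr, 100)
    expect_equal(res$ani_two_way, 95.0, tolerance = 0.5 / 95)
    # symmetry under argument swap
    swapped <- twoWayANI(mut, big)
    expect_equal(swapped$ani_two_way, res$ani_two_way)
})

test_that("ANI decreases monotonically with the substitution rate", {
    g <- generateAncestor(60000, 0.6, seed = 51, strain_id = "g")
    rates <- c(0.01, 0.05, 0.10, 0.15)
    anis <- vapply(seq_along(rates), function(i)
        twoWayANI(g, evolveGenome(g, rates[[i]], seed = 60 + i,
                                  strain_id = paste0("m", i)))$ani_two_way,
        numeric(1))
    expect_true(all(diff(anis) < 0))
    expect_equal(anis, 100 * (1 - rates), tolerance = 0.01)
})

test_that("ANI matrices are symmetric with planted clade structure", {
    g <- generateAncestor(25000, 0.6, seed = 71, strain_id = "a")
    copies <- list(g,
        genomeRecord("b", stats::setNames(as.character(contigs(g)), "b_c1")),
        genomeRecord("c", stats::setNames(as.character(contigs(g)), "c_c1")))
    m_id <- aniValues(aniMatrix(copies))
    expect_true(all(abs(m_id - 100) < 1e-9))

    panel <- generatePanel(n_per_clade = c(3, 3), within_identity = 0.97,
                           between_identity = 0.85, genome_length = 30000,
                           seed = 72)
    m <- aniMatrix(panel$genomes)
    v <- aniValues(m)
    expect_equal(v, t(v))
    expect_true(all(diag(v) == 100))
    same <- outer(panel$truth, panel$truth, "==")
    off <- upper.tri(v)
    expect_true(all(v[off & same] > 95))
    expect_true(all(v[off & !same] < 95))
    expect_true(min(v[off & same]) > max(v[off & !same]))
})
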