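test_that("ANI converts to clustering distances on the fractional scale", {
    expect_equal(aniToDistance(matrix(100, 1, 1,
        dimnames = list("a", "a")))[1, 1], 0)
    m <- matrix(c(100, 91.16, 91.16, 100), 2,
                dimnames = list(c("a", "b"), c("a", "b")))
    d <- aniToDistance(m)
    expect_equal(d["a", "b"], 0.0884)
    expect_equal(d, t(d))
    expect_true(all(d >= 0))
    m[1, 2] <- m[2, 1] <- NA
    expect_error(aniToDistance(m), "missing")
})

make_block_ani <- function(within, between) {
    ids <- paste0("s", 1:4)
    m <- matrix(between, 4, 4, dimnames = list(ids, ids))
    m[1:2, 1:2] <- within; m[3:4, 3:4] <- within
    diag(m) <- 100
    m
}

test_that("threshold cuts extract the expected ANI clusters", {
    m <- make_block_ani(96, 80)
    cl95 <- cutClusters(m, 95)
    expect_equal(length(unique(cl95)), 2)
    expect_equal(cl95[["s1"]], cl95[["s2"]])
    expect_equal(cl95[["s3"]], cl95[["s4"]])
    expect_true(cl95[["s1"]] != cl95[["s3"]])

    cl99 <- cutClusters(m, 99)
    expect_equal(length(unique(cl99)), 4)

    # a partition: every strain in exactly one cluster
    expect_setequal(names(cl95), rownames(m))
    expect_false(anyNA(cl95))

    # raising the threshold never merges clusters (refinement property)
    for (thr in c(70, 85, 90, 97, 99.5)) {
        lo <- cutClusters(m, thr - 5)
        hi <- cutClusters(m, thr)
        # hi must refine lo: same hi-cluster implies same lo-cluster
        for (u in unique(hi)) {
            members <- names(hi)[hi == u]
            expect_equal(length(unique(lo[members])), 1)
        }
    }
})

test_that("the decision engine resolves the reference panel's landmark strains", {
    ev <- evidenceFixture()
    dec <- decideClassification(ev)

    nh9 <- dec[dec$strain_id == "NH9", ]
    expect_equal(nh9$proposed_genus, "Cupriavidus")
    expect_equal(nh9$proposed_species, "necator")
    expect_false(nh9$changed)
    expect_equal(nh9$flag_pocp, "agree")
    expect_equal(nh9$flag_ani, "agree")

    dtp <- dec[dec$strain_id == "DTP0602", ]
    expect_equal(dtp$proposed_genus, "Cupriavidus")
    expect_equal(dtp$proposed_species, "sp.")
    expect_true(dtp$changed)
    expect_equal(dtp$flag_16s, "conflict")  # its 16S clade says C. necator

    pba <- dec[dec$strain_id == "PBA", ]
    expect_equal(pba$proposed_genus, "other")
    expect_true(pba$changed)

    a12 <- dec[dec$strain_id == "A12", ]
    expect_equal(a12$proposed_species, "insidiosa")
    expect_equal(a12$flag_ani, "conflict")  # singleton ANI cluster

    # phylotype override inside the species complex
    cqps <- dec[dec$strain_id == "CQPS-1", ]
    expect_equal(cqps$proposed_species, "pseudosolanacearum")
    kacc <- dec[dec$strain_id == "KACC 10722", ]
    expect_equal(kacc$proposed_species, "syzygii")
})

test_that("decisions are order-independent and count correctly", {
    ev <- evidenceFixture()
    dec <- decideClassification(ev)
    expect_equal(countReclassified(dec) + sum(!dec$changed), nrow(ev))

    shuffled <- withSeed(401, ev[sample(nrow(ev)), ])
    dec2 <- decideClassification(shuffled)
    dec2 <- dec2[match(dec$strain_id, dec2$strain_id), ]
    rownames(dec2) <- NULL
    expect_equal(dec2, dec)

    expect_error(countReclassified(rbind(dec, dec[1, ])), "duplicate")

    # all-confirming evidence yields zero changes
    confirm <- data.frame(strain_id = c("x", "y", "z"),
        current_genus = "Cupriavidus",
        current_species = c("necator", "necator", "sp."),
        type_strain = c(TRUE, FALSE, FALSE),
        phylotype = NA_character_,
        ani_cluster = c(1, 1, 2), tna_cluster = c("A", "A", "B"),
        pocp_genus = "Cupriavidus", stringsAsFactors = FALSE)
    expect_equal(countReclassified(decideClassification(confirm)), 0)
})

test_that("the engine recovers planted truth end to end", {
    # two genera x two species x two strains descending from one root:
    # strains of a species at ANI ~97, species within a genus ~85, genera
    # ~72 (still alignable), so every evidence layer carries signal
    root <- generateAncestor(30000, 0.6, seed = 410, strain_id = "root")
    ids <- c(paste0("A", 1:4), paste0("B", 1:4))
    genomes <- list(); k <- 0
    for (gi in 1:2) {
        ganc <- evolveGenome(root, 0.08, seed = 410 + gi,
                             strain_id = paste0("g", gi))
        for (si in 1:2) {
            sanc <- evolveGenome(ganc, 0.065, seed = 420 + 2 * gi + si,
                                 strain_id = paste0("g", gi, "s", si))
            for (st in 1:2) {
                k <- k + 1
                genomes[[ids[[k]]]] <- evolveGenome(
                    sanc, 0.015, seed = 430 + k, strain_id = ids[[k]])
            }
        }
    }

    genus_of <- rep(c("GenusA", "GenusB"), each = 4)
    species_of <- c("alpha", "alpha", "beta", "beta",
                    "gamma", "gamma", "delta", "delta")
    metadata <- data.frame(strain_id = ids, current_genus = genus_of,
        current_species = species_of,
        type_strain = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
        phylotype = NA_character_, stringsAsFactors = FALSE)

    ani <- aniMatrix(genomes)
    v <- aniValues(ani)
    # sanity: planted identity structure on the ANI scale
    expect_gt(min(v["A1", "A2"], v["A3", "A4"]), 93)
    expect_lt(v["A1", "A3"], 90)
    expect_lt(v["A1", "B1"], v["A1", "A3"])

    # proteomes: 45% universal core, +30% genus core, 25% strain-specific
    make_prot <- function(universal, genus_core, seed) {
        withSeed(seed, {
            core <- vapply(c(universal, genus_core), function(p)
                taxongauge:::.mutateProtein(p, 0.03), character(1))
            spec <- vapply(1:5, function(i) taxongauge:::.randomProtein(180),
                           character(1))
            c(core, spec)
        })
    }
    universal <- withSeed(413, vapply(1:9, function(i)
        taxongauge:::.randomProtein(200), character(1)))
    coreA <- withSeed(414, vapply(1:6, function(i)
        taxongauge:::.randomProtein(200), character(1)))
    coreB <- withSeed(415, vapply(1:6, function(i)
        taxongauge:::.randomProtein(200), character(1)))
    proteomes <- lapply(seq_along(ids), function(i)
        proteomeRecord(ids[[i]], stats::setNames(
            make_prot(universal, if (i <= 4) coreA else coreB, 420 + i),
            paste0(ids[[i]], "_p", 1:20))))
    names(proteomes) <- ids

    refs <- list(GenusA = proteomes[c("A1", "A3")],
                 GenusB = proteomes[c("B1", "B3")])
    pocp_calls <- vapply(ids, function(s) {
        means <- vapply(refs, function(grp)
            meanPocpVsGroup(proteomes[[s]], grp), numeric(1))
        genusCall(s, means)$call
    }, character(1))
    expect_equal(unname(pocp_calls), genus_of)

    profiles <- lapply(genomes, tetraProfile)
    emb <- pcaEmbed(profiles, k = 3)
    hc <- stats::hclust(stats::dist(pcaScores(emb)), method = "average")
    tna <- clusterEmbedding(emb, mean(sort(hc$height, decreasing = TRUE)[1:2]))

    thresholds <- thresholdConfig(ani_cupriavidus = 90,
                                  ani_ralstonia_default = 90)
    ev <- buildEvidence(metadata, ani, tna, pocp_calls, thresholds)
    dec <- decideClassification(ev, thresholds)
    expect_equal(dec$proposed_genus, genus_of)
    agree <- dec$proposed_species == species_of
    expect_gte(mean(agree), 0.95)
    expect_equal(countReclassified(dec), 0)
})
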