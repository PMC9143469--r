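test_that("identical configurations yield byte-identical artifacts", {
    cfg <- simulationConfig(seed = 19L, nGenomes = 2L, nFamilies = 3L,
                            meanCopies = 1.5, clustersPerGenome = 1L,
                            maxPerCluster = 2L,
                            clusterSizeWeights = c(0.5, 0.5),
                            forceMaxCluster = FALSE)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    simulateCypome(cfg, dir = d1)
    simulateCypome(cfg, dir = d2)
    f1 <- sort(list.files(d1))
    expect_equal(f1, sort(list.files(d2)))
    for (f in f1)
        expect_equal(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("simulated panel archetypes are mutually dissimilar with motifs", {
    sim <- smallSim()
    panel <- sim$panel
    seqs <- as.character(panelSequences(panel))
    for (i in seq_len(length(seqs) - 1)) for (j in seq(i + 1, length(seqs)))
        expect_lt(pairwiseIdentity(seqs[[i]], seqs[[j]])$identity_pct, 40)
    for (s in seqs) {
        ev <- findMotifs(s, motifConfig())
        expect_true(ev$has_exxr && ev$has_cxg && ev$ordered)
    }
})

test_that("planted P450 identities lie strictly inside their bands", {
    sim <- smallSim()
    cfg <- simulationConfig(seed = 11L, nGenomes = 3L, nFamilies = 4L,
                            meanCopies = 2, clustersPerGenome = 2L,
                            maxPerCluster = 3L,
                            clusterSizeWeights = c(0.5, 0.3, 0.2))
    p450 <- sim$truth[sim$truth$type == "P450", ]
    arch <- setNames(as.character(panelSequences(sim$panel)),
                     unname(panelFamily(sim$panel)))
    for (i in seq_len(nrow(p450))) {
        band <- cfg$bands[[p450$band[i]]]
        # stored measurement in band
        expect_gt(p450$identity_to_archetype[i], band[1])
        expect_lt(p450$identity_to_archetype[i], band[2])
        # independent re-measurement agrees
        s <- sim$records$sequence[sim$records$id == p450$id[i]]
        remeas <- pairwiseIdentity(s, arch[[p450$family[i]]])$identity_pct
        expect_equal(remeas, p450$identity_to_archetype[i])
    }
})

test_that("planted fragments and decoys classify as planted", {
    sim <- smallSim()
    calls <- classifyProteins(sim$records)
    truth <- sim$truth$type[match(calls$id, sim$truth$id)]
    expect_equal(calls$status[truth == "P450"],
                 rep("P450", sum(truth == "P450")))
    expect_equal(calls$status[truth == "fragment"],
                 rep("fragment", sum(truth == "fragment")))
    expect_equal(calls$status[truth == "decoy"],
                 rep("non-P450", sum(truth == "decoy")))
})

test_that("cluster plan respects the configured maximum and residuals", {
    an <- defaultSimAnalysis()
    sizes <- table(an$sim$membership$cluster_id)
    expect_equal(max(sizes), an$config$maxPerCluster)
    # some P450s stay outside all clusters in every genome
    p450_ids <- an$sim$truth$id[an$sim$truth$type == "P450"]
    expect_gt(length(setdiff(p450_ids, an$sim$membership$gene_id)), 0)
})

test_that("zero clusters per genome yields an empty cluster table", {
    cfg <- simulationConfig(seed = 29L, nGenomes = 2L, nFamilies = 3L,
                            meanCopies = 1.5, clustersPerGenome = 0L,
                            maxPerCluster = 2L,
                            clusterSizeWeights = c(0.5, 0.5),
                            forceMaxCluster = FALSE)
    sim <- simulateCypome(cfg)
    expect_equal(nrow(sim$clusters), 0)
    expect_equal(nrow(sim$membership), 0)
})

test_that("full pipeline recovers the planted ground truth at scale", {
    an <- defaultSimAnalysis()
    sim <- an$sim
    truth <- sim$truth

    # fragment statuses: 100% recovery
    calls <- an$calls
    tmap <- truth$type[match(calls$id, truth$id)]
    expect_equal(calls$status[tmap == "fragment"],
                 rep("fragment", sum(tmap == "fragment")))
    expect_equal(calls$status[tmap == "P450"],
                 rep("P450", sum(tmap == "P450")))

    # family labels: >= 99% of planted labels recovered (novel plants count
    # as recovered when founded as a new family)
    m <- merge(an$assignments, truth, by.x = "query_id", by.y = "id")
    ok <- ifelse(m$band == "new", m$basis == "new-family",
                 m$family.x == m$family.y &
                     ifelse(m$band == "subfamily",
                            m$basis == "subfamily-match",
                            m$basis == "family-match"))
    expect_gte(mean(ok), 0.99)

    # cluster memberships: 100% recovery
    got <- an$linkage$memberships[, c("cluster_id", "gene_id")]
    got <- got[order(got$cluster_id, got$gene_id), ]
    want <- sim$membership[order(sim$membership$cluster_id,
                                 sim$membership$gene_id), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
    expect_equal(maxP450sPerCluster(an$linkage$signatures),
                 an$config$maxPerCluster)
})
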