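toyGenes <- function() {
    data.frame(
        gene_id = c("a", "b", "c", "d"),
        genome_id = "g1", contig_id = "c1",
        start = c(100L, 2000L, 19900L, 30000L),
        end = c(1300L, 3100L, 21100L, 31200L),
        label = c("CYP105AB", "CYP107AW", "CYP244A", "CYP245A"),
        stringsAsFactors = FALSE)
}

toyClusters <- function() {
    data.frame(
        genome_id = "g1", contig_id = "c1",
        cluster_id = c("bgc1", "bgc2"),
        bgc_type = c("NRPS", "T1PKS"),
        start = c(50L, 29000L), end = c(20000L, 35000L),
        stringsAsFactors = FALSE)
}

test_that("cluster membership is by full containment, ordered by start", {
    res <- assignP450sToClusters(toyGenes(), toyClusters())
    sig <- res$signatures
    # gene [100,1300] inside [50,20000]; gene [19900,21100] spans the end
    expect_equal(sig$signature[sig$cluster_id == "bgc1"],
                 "CYP105AB,CYP107AW")
    expect_equal(sig$n_p450, c(2L, 1L))
    expect_equal(res$residual, "c")
    # any-overlap mode admits the boundary-spanning gene
    res2 <- assignP450sToClusters(toyGenes(), toyClusters(), overlap = TRUE)
    expect_equal(res2$signatures$signature[1], "CYP105AB,CYP107AW,CYP244A")
})

test_that("containment is symmetric under coordinate mirroring", {
    genes <- toyGenes()
    clusters <- toyClusters()
    M <- 50000L
    mg <- genes
    mg$start <- M - genes$end + 1L
    mg$end <- M - genes$start + 1L
    mc <- clusters
    mc$start <- M - clusters$end + 1L
    mc$end <- M - clusters$start + 1L
    res <- assignP450sToClusters(genes, clusters)
    mres <- assignP450sToClusters(mg, mc)
    for (cid in clusters$cluster_id) {
        a <- res$memberships$gene_id[res$memberships$cluster_id == cid]
        b <- mres$memberships$gene_id[mres$memberships$cluster_id == cid]
        expect_equal(sort(a), sort(b))
        # gene order along the contig reverses under mirroring
        expect_equal(a, rev(b))
    }
    expect_equal(sort(res$residual), sort(mres$residual))
})

test_that("a gene inside overlapping clusters joins both, with a warning", {
    genes <- toyGenes()[1, ]
    clusters <- rbind(toyClusters(),
                      data.frame(genome_id = "g1", contig_id = "c1",
                                 cluster_id = "bgc3", bgc_type = "Indole",
                                 start = 1L, end = 5000L))
    expect_warning(res <- assignP450sToClusters(genes, clusters), "multiple")
    expect_equal(sum(res$memberships$gene_id == "a"), 2)
})

test_that("type aggregation reproduces the published cluster table totals", {
    fx <- loadFixtureTables()
    sigs <- fixtureSignatures(fx$table4)
    agg <- aggregateByType(sigs)
    t <- agg$types
    get <- function(tp, col) t[t$bgc_type == tp, col]
    expect_equal(get("Indole", "n_p450_total"), 105)
    expect_equal(get("T1PKS", "n_clusters"), 223)
    expect_equal(get("T1PKS", "n_p450_total"), 275)
    expect_equal(get("oligosaccharide", "n_p450_total"), 121)
    expect_equal(get("NRPS", "n_p450_total"), 395)
    # variety counts within a type sum to its cluster count
    v <- agg$varieties
    expect_equal(vapply(t$bgc_type, function(tp)
        sum(v$n_clusters[v$bgc_type == tp]), integer(1)),
        setNames(t$n_clusters, t$bgc_type))
    # total cluster-member P450s across all types
    expect_equal(sum(t$n_p450_total), 1236)
    # empty input aggregates to empty
    empty <- sigs[0, ]
    expect_equal(nrow(aggregateByType(empty)$types), 0)
})

test_that("maximum P450 load per cluster", {
    fx <- loadFixtureTables()
    sigs <- fixtureSignatures(fx$table4)
    expect_equal(maxP450sPerCluster(sigs), 6)
    singles <- sigs[sigs$n_p450 == 1, ]
    expect_equal(maxP450sPerCluster(singles), 1)
    expect_error(maxP450sPerCluster(sigs[0, ]), "no cluster")
})

test_that("family breakdown counts members by leading CYP+digits", {
    sigs <- data.frame(
        cluster_id = c("c1", "c2"), genome_id = "g", bgc_type = "NRPS",
        signature = c("CYP107AW,CYP107AW,CYP105G", "CYP107AW"),
        n_p450 = c(3L, 1L), stringsAsFactors = FALSE)
    bd <- bgcFamilyBreakdown(sigs)
    expect_equal(bd$family, c("CYP107", "CYP105"))
    expect_equal(bd$count, c(3L, 1L))
    expect_equal(bd$pct, c(75, 25))
    expect_equal(nrow(bgcFamilyBreakdown(sigs[0, ])), 0)
    bad <- sigs
    bad$signature[1] <- "FOO1,CYP107AW"
    expect_error(bgcFamilyBreakdown(bad), "FOO1")
})

test_that("fragment-suffixed fixture labels can be excluded", {
    fx <- loadFixtureTables()
    with_frag <- fixtureSignatures(fx$table4)
    without <- fixtureSignatures(fx$table4, includeFragments = FALSE)
    expect_true(any(grepl("-fragment", with_frag$signature)))
    expect_false(any(grepl("-fragment", without$signature)))
    expect_lt(sum(without$n_p450), sum(with_frag$n_p450))
})

test_that("cluster tables round-trip and reject duplicates", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeBgcTable(toyClusters(), f)
    expect_equal(readBgcTable(f), toyClusters())
    dup <- rbind(toyClusters(), toyClusters()[1, ])
    writeBgcTable(dup, f)
    expect_error(readBgcTable(f), "duplicate")
})
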