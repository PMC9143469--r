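# minimal hand-built calls/assignments for counting checks
toyCallsAssignments <- function() {
    calls <- data.frame(
        id = sprintf("p%d", 1:8),
        genome_id = c(rep("g1", 5), rep("g2", 2), "g3"),
        status = c(rep("P450", 5), "P450", "fragment", "non-P450"),
        stringsAsFactors = FALSE)
    asg <- data.frame(
        query_id = sprintf("p%d", 1:6),
        genome_id = calls$genome_id[1:6],
        family = c("CYP105", "CYP105", "CYP105", "CYP107", "CYP107",
                   "CYP105"),
        stringsAsFactors = FALSE)
    list(calls = calls, asg = asg)
}

test_that("profile counts P450s per genome and family", {
    t <- toyCallsAssignments()
    prof <- buildProfile(t$asg, t$calls)
    m <- profileCounts(prof)
    expect_equal(m["g1", c("CYP105", "CYP107")], c(CYP105 = 3L, CYP107 = 2L))
    expect_equal(m["g2", ], c(CYP105 = 1L, CYP107 = 0L))
    # genome with no P450s keeps its all-zero row
    expect_equal(unname(m["g3", ]), c(0L, 0L))
    # fragments tallied per genome from calls
    expect_equal(fragmentCounts(prof), c(g1 = 0L, g2 = 1L, g3 = 0L))
    # conservation: total count equals number of complete P450 calls
    expect_equal(sum(m), sum(t$calls$status == "P450"))
    expect_error(buildProfile(t$asg[-1, ], t$calls), "cover")
    bad <- t$asg
    bad$query_id[1] <- "ghost"
    expect_error(buildProfile(bad, t$calls), "unknown")
})

test_that("summary statistics implement the three closed-form formulas", {
    s <- cypomeStats(nP450 = 2643, nSpecies = 126, nSpeciesWithP450 = 126,
                     nFamilies = 45, nSubfamilies = 103, nInBgc = 1236)
    expect_equal(s$avg_p450, 2643 / 126)
    expect_equal(s$diversity_pct, 100 * 45 / (2643 * 126))
    expect_equal(s$pct_in_bgc, 100 * 1236 / 2643)
    f <- formatStats(s)
    expect_equal(f$avg_p450, 21)
    expect_equal(f$diversity_pct, 0.01)
    expect_equal(f$pct_in_bgc, 47)
    # raw values retained unrounded
    expect_false(s$avg_p450 == 21)
    expect_error(cypomeStats(0, 10, 0, 0, 0), "undefined")
    expect_error(cypomeStats(10, 0, 10, 1, 1), "undefined")
})

test_that("computeStats derives inputs from the profile", {
    t <- toyCallsAssignments()
    prof <- buildProfile(t$asg, t$calls)
    s <- computeStats(prof, nSubfamilies = 4)
    expect_equal(s$n_p450, 6)
    expect_equal(s$n_species, 3)
    expect_equal(s$n_species_with_p450, 2)
    expect_equal(s$n_families, 2)
    expect_true(is.na(s$pct_in_bgc))
})

test_that("bloom detection flags multi-copy families at the thresholds", {
    m <- matrix(c(3L, 3L, 4L,   # bloomed: >=3 in all genomes
                  1L, 1L, 1L,   # single-copy everywhere
                  3L, 1L, 1L),  # >=3 in 1/3 genomes only
                nrow = 3,
                dimnames = list(paste0("g", 1:3), c("FA", "FB", "FC")))
    prof <- new("CypomeProfile", counts = m,
                fragments = setNames(integer(3), rownames(m)))
    expect_equal(detectBloomed(prof), "FA")
    expect_equal(detectBloomed(prof, genomeFracMin = 1 / 3), c("FA", "FC"))
})

test_that("uniformly spread published family totals flag the two largest", {
    fx <- loadFixtureTables()
    famtab <- fx$table3[!duplicated(fx$table3$family), ]
    n_genomes <- nrow(fx$table2)
    counts <- vapply(famtab$family_count, function(tot)
        rep(as.integer(round(tot / n_genomes)), n_genomes),
        integer(n_genomes))
    dimnames(counts) <- list(fx$table2$species, famtab$family)
    prof <- new("CypomeProfile", counts = counts,
                fragments = setNames(integer(n_genomes), rownames(counts)))
    # only families averaging >= 3 copies per genome qualify at defaults
    expect_equal(sort(detectBloomed(prof)), c("CYP105", "CYP107"))
})

test_that("conservation detection applies the presence fraction", {
    m <- matrix(c(rep(1L, 126),
                  c(rep(1L, 125), 0L),
                  c(rep(1L, 122), 0L, 0L, 0L, 0L)),
                nrow = 126,
                dimnames = list(sprintf("g%03d", 1:126),
                                c("FA", "FB", "FC")))
    prof <- new("CypomeProfile", counts = m,
                fragments = setNames(integer(126), rownames(m)))
    expect_equal(detectConserved(prof), "FA")
    # 122/126 ~ 0.968 passes a 0.95 threshold
    expect_equal(detectConserved(prof, presenceFracMin = 0.95),
                 c("FA", "FB", "FC"))
})

test_that("heat-map encodes presence as 3/-3 and clusters structure", {
    m <- matrix(c(2L, 3L, 0L, 0L,
                  1L, 1L, 0L, 0L,
                  0L, 0L, 5L, 1L,
                  0L, 0L, 2L, 2L),
                nrow = 4, byrow = TRUE,
                dimnames = list(paste0("g", 1:4), paste0("F", 1:4)))
    prof <- new("CypomeProfile", counts = m,
                fragments = setNames(integer(4), rownames(m)))
    hm <- clusterHeatmap(prof)
    v <- heatmapValues(hm)
    expect_true(all(v %in% c(-3, 3)))
    expect_equal(v == 3, m > 0, ignore_attr = TRUE)
    # two disjoint family blocks: the top-level split separates g1,g2 | g3,g4
    grp <- stats::cutree(hm@rowDendro, k = 2)
    expect_equal(grp[["g1"]], grp[["g2"]])
    expect_equal(grp[["g3"]], grp[["g4"]])
    expect_false(grp[["g1"]] == grp[["g3"]])
    # identical rows sit adjacent in the ordering
    prof2 <- new("CypomeProfile",
                 counts = m[c(1, 3, 2, 4), ],
                 fragments = setNames(integer(4),
                                      rownames(m)[c(1, 3, 2, 4)]))
    hm2 <- clusterHeatmap(prof2)
    ord <- rownames(heatmapValues(hm2))[heatmapRowOrder(hm2)]
    expect_equal(abs(diff(match(c("g1", "g2"), ord))), 1)
})

test_that("degenerate and undersized profiles are handled", {
    all1 <- matrix(1L, 2, 2, dimnames = list(c("g1", "g2"), c("FA", "FB")))
    prof <- new("CypomeProfile", counts = all1,
                fragments = setNames(integer(2), c("g1", "g2")))
    expect_warning(hm <- clusterHeatmap(prof), "degenerate")
    expect_equal(heatmapRowOrder(hm), 1:2)
    one <- new("CypomeProfile",
               counts = matrix(1L, 2, 1,
                               dimnames = list(c("g1", "g2"), "FA")),
               fragments = setNames(integer(2), c("g1", "g2")))
    expect_error(clusterHeatmap(one), ">= 2")
})
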