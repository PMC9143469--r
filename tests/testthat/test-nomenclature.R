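test_that("percent identity: exact and near-exact cases", {
    s <- "MAEELLRAGTMAEELLRAGT"
    expect_equal(pairwiseIdentity(s, s)$identity_pct, 100)
    # one conservative substitution in 10 residues, gap-free alignment
    a <- "MAEELLRAGT"
    b <- "MAEEILRAGT"
    r <- pairwiseIdentity(a, b)
    expect_equal(r$identity_pct, 90)
    expect_equal(r$n_aligned_pairs, 10)
    expect_error(pairwiseIdentity("", a), "non-empty")
})

test_that("identity equals a column walk over the emitted alignment", {
    set.seed(13)
    for (trial in 1:60) {
        a <- randomProtein(50)
        b <- randomProtein(50)
        r <- pairwiseIdentity(a, b)
        oracle <- columnWalkIdentity(r$aligned_a, r$aligned_b)
        expect_equal(r$identity_pct, oracle$identity_pct)
        expect_equal(r$n_aligned_pairs, oracle$n_aligned_pairs)
    }
})

test_that("identity is symmetric", {
    set.seed(17)
    for (trial in 1:10) {
        a <- randomProtein(80)
        b <- mutateProtein(a, sample(5:60, 1))
        expect_equal(pairwiseIdentity(a, b)$identity_pct,
                     pairwiseIdentity(b, a)$identity_pct,
                     tolerance = 1e-9)
    }
})

test_that("nomenclature thresholds use strict inequalities", {
    expect_equal(assignmentBasis(c(39.9, 40, 40.1, 55, 55.1, 100)),
                 c("new-family", "new-family", "family-match",
                   "family-match", "subfamily-match", "subfamily-match"))
})

test_that("panel members assigned against the panel recover themselves", {
    sim <- smallSim()
    panel <- sim$panel
    calls <- classifyProteins(
        recordsFromSequences(as.character(panelSequences(panel))))
    asg <- assignFamilies(calls, panel)
    expect_equal(asg$best_identity_pct, rep(100, length(panel)))
    expect_equal(asg$basis, rep("subfamily-match", length(panel)))
    expect_equal(asg$family, unname(panelFamily(panel)))
    expect_equal(asg$subfamily, unname(panelSubfamily(panel)))
})

test_that("ties at best identity resolve to the smallest reference name", {
    s <- makeP450Sequence(360, seed = 21)
    panel <- referencePanel(c(CYP9902B1 = s, CYP9901A1 = s))
    q <- recordsFromSequences(c(q1 = mutateProtein(s, 30,
                                                   motifPositions(360))))
    asg <- assignFamilies(classifyProteins(q), panel)
    expect_equal(asg$best_hit, "CYP9901A1")
    expect_equal(asg$family, "CYP9901")
})

test_that("queries in planted identity bands recover the planted labels", {
    sim <- smallSim()
    calls <- classifyProteins(sim$records)
    asg <- assignFamilies(calls, sim$panel)
    m <- merge(asg, sim$truth, by.x = "query_id", by.y = "id")
    expect_equal(nrow(m), sum(sim$truth$type == "P450"))
    # basis always consistent with the measured best identity
    expect_equal(m$basis, assignmentBasis(m$best_identity_pct))
    # subfamily- and family-band plants recover the planted family
    known <- m$band %in% c("subfamily", "family")
    expect_true(all(m$family.x[known] == m$family.y[known]))
    expect_true(all(m$basis[m$band == "subfamily"] == "subfamily-match"))
    expect_true(all(m$basis[m$band == "family"] == "family-match"))
    expect_true(all(m$basis[m$band == "new"] == "new-family"))
})

test_that("novel queries group by single-linkage at the family threshold", {
    set.seed(23)
    sim <- smallSim()
    base1 <- makeP450Sequence(420)
    base2 <- makeP450Sequence(420)
    frozen <- motifPositions(420)
    # two tight pairs plus one singleton, all far below 40% to the panel
    queries <- c(n1 = base1, n2 = mutateProtein(base1, 40, frozen),
                 n3 = base2, n4 = mutateProtein(base2, 40, frozen),
                 n5 = makeP450Sequence(420))
    calls <- classifyProteins(recordsFromSequences(queries))
    asg <- assignFamilies(calls, sim$panel)
    expect_true(all(asg$basis == "new-family"))
    # brute-force oracle: connected components of the >40% identity graph
    n <- length(queries)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        adj[i, j] <- adj[j, i] <-
            pairwiseIdentity(queries[[i]], queries[[j]])$identity_pct > 40
    }
    comp <- seq_len(n)
    repeat {
        new <- vapply(seq_len(n), function(i)
            min(comp[c(i, which(adj[i, ]))]), integer(1))
        if (identical(new, comp)) break
        comp <- new
    }
    oracle_partition <- split(names(queries), comp)
    got_partition <- split(asg$query_id, asg$family)
    # same grouping, order-insensitive comparison
    canon <- function(p) unname(sort(vapply(p, function(g)
        paste(sort(g), collapse = "+"), character(1))))
    expect_equal(canon(oracle_partition), canon(got_partition))
    # placeholder numbering follows first occurrence in input order
    expect_equal(asg$family[1], "CYPNEW-1")
})

test_that("degenerate inputs error cleanly", {
    sim <- smallSim()
    calls <- classifyProteins(sim$records)
    empty <- referencePanel(setNames(character(), character()))
    expect_error(assignFamilies(calls, empty), "empty")
    none <- calls[calls$status == "never", ]
    expect_equal(nrow(assignFamilies(none, sim$panel)), 0)
})
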