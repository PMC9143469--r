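# shared fixture builders; everything is generated in code under fixed seeds

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

randomProtein <- function(n, alphabet = AA20) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# full-length P450-like sequence with window-compliant ordered motifs
makeP450Sequence <- function(len = 420L, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    v <- sample(setdiff(AA20, c("E", "C")), len, replace = TRUE)
    e <- round(0.7 * len)
    v[e:(e + 3L)] <- c("E", "A", "A", "R")
    cx <- len - 60L
    v[cx:(cx + 2L)] <- c("C", "A", "G")
    paste(v, collapse = "")
}

# substitute k positions (never touching `frozen`) with a different residue
mutateProtein <- function(seq, k, frozen = integer()) {
    v <- strsplit(seq, "")[[1]]
    free <- setdiff(seq_along(v), frozen)
    pos <- sample(free, min(k, length(free)))
    for (p in pos) v[p] <- sample(setdiff(AA20, v[p]), 1)
    paste(v, collapse = "")
}

# motif positions of makeP450Sequence output, for freezing
motifPositions <- function(len = 420L) {
    e <- round(0.7 * len)
    cx <- len - 60L
    c(e:(e + 3L), cx:(cx + 2L))
}

# independent column-walk over a gapped alignment pair
columnWalkIdentity <- function(alignedA, alignedB) {
    a <- strsplit(alignedA, "")[[1]]
    b <- strsplit(alignedB, "")[[1]]
    stopifnot(length(a) == length(b))
    keep <- a != "-" & b != "-"
    list(identity_pct = 100 * sum(a[keep] == b[keep]) / sum(keep),
         n_aligned_pairs = sum(keep))
}

# protein record data.frame from bare sequences
recordsFromSequences <- function(seqs, genome = "g1", contig = "c1",
                                 gap = 200L) {
    pos <- 1L
    rows <- lapply(seq_along(seqs), function(i) {
        len_nt <- 3L * nchar(seqs[[i]])
        r <- data.frame(id = names(seqs)[i] %||% sprintf("p%03d", i),
                        genome_id = genome, contig_id = contig,
                        start = pos, end = pos + len_nt - 1L, strand = "+",
                        sequence = seqs[[i]], stringsAsFactors = FALSE)
        pos <<- pos + len_nt + gap
        r
    })
    do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small simulated study shared across test files
smallSim <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            cfg <- simulationConfig(seed = 11L, nGenomes = 3L,
                                    nFamilies = 4L, meanCopies = 2,
                                    clustersPerGenome = 2L,
                                    maxPerCluster = 3L,
                                    clusterSizeWeights = c(0.5, 0.3, 0.2))
            cache <<- simulateCypome(cfg)
        }
        cache
    }
})

# the default-scale simulated study (10 genomes, 6 families, ~200 P450s)
# with the full pipeline run over it; computed once per test run
defaultSimAnalysis <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            cfg <- simulationConfig(seed = 42L)
            sim <- simulateCypome(cfg)
            calls <- classifyProteins(sim$records)
            assignments <- assignFamilies(calls, sim$panel)
            genes <- p450GeneTable(calls, assignments)
            linkage <- assignP450sToClusters(genes, sim$clusters)
            cache <<- list(config = cfg, sim = sim, calls = calls,
                           assignments = assignments, genes = genes,
                           linkage = linkage)
        }
        cache
    }
})
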