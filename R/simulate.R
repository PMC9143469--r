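.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")

# default smBGC type frequencies, mirroring the packaged fixture's 18 types
.BGC_TYPE_COUNTS <- c(
    Bacteriocin = 47, betalactone = 2, butyrolactone = 1, Indole = 54,
    ladderane = 18, lanthipeptide = 2, LAP = 1, lipolanthine = 2,
    NRPS = 205, `NRPS-like` = 30, oligosaccharide = 35, other = 4,
    T1PKS = 223, T2PKS = 76, T3PKS = 8, Terpene = 61, `transAT-PKS` = 1,
    `transAT-PKS-like` = 8)

#' Simulation configuration
#'
#' Parameters of the synthetic-CYPome generator. Defaults describe the
#' study conditions the package is tested under: 10 genomes carrying 6
#' P450 families at ~3.3 copies each (~200 complete P450s in total, ~20
#' per genome), a ~5% fragment rate, and up to 3 clusters per genome with
#' 1-6 member P450s, type frequencies mirroring the packaged smBGC table.
#' Identity bands keep a >= 2 percentage-point margin around the 40% and
#' 55% nomenclature thresholds so planted band membership is unambiguous.
#'
#' @param seed integer RNG seed; every simulated artifact is a
#'   deterministic function of the full configuration including the seed.
#' @param nGenomes,nFamilies genome and family counts.
#' @param archetypeLength archetype length in residues (default 420, a
#'   typical bacterial P450 length).
#' @param meanCopies mean per-genome copy count per family (Poisson).
#' @param bands named list of `c(lo, hi)` percent-identity bands for
#'   `subfamily` (> 55), `family` (40-55) and `new` (< 40) plants.
#' @param bandWeights sampling weights over the three bands.
#' @param fragmentRate expected fragments per complete P450.
#' @param decoysPerGenome motif-free non-P450 proteins per genome.
#' @param clustersPerGenome clusters attempted per genome.
#' @param maxPerCluster maximum P450s in one cluster (<= 6).
#' @param clusterSizeWeights sampling weights for cluster sizes
#'   `1..maxPerCluster`.
#' @param bgcTypeWeights named weights over cluster type labels.
#' @param forceMaxCluster plant one cluster of exactly `maxPerCluster`
#'   members in the first genome so the simulated maximum is known.
#' @return a list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L, nGenomes = 10L, nFamilies = 6L,
                             archetypeLength = 420L, meanCopies = 3.3,
                             bands = list(subfamily = c(60, 92),
                                          family = c(43, 53),
                                          new = c(15, 38)),
                             bandWeights = c(subfamily = 0.8,
                                             family = 0.15, new = 0.05),
                             fragmentRate = 0.05, decoysPerGenome = 5L,
                             clustersPerGenome = 3L, maxPerCluster = 6L,
                             clusterSizeWeights = c(0.35, 0.3, 0.15, 0.1,
                                                    0.06, 0.04),
                             bgcTypeWeights = .BGC_TYPE_COUNTS,
                             forceMaxCluster = TRUE) {
    stopifnot(maxPerCluster >= 1, maxPerCluster <= 6,
              length(clusterSizeWeights) == maxPerCluster,
              all(names(bands) == c("subfamily", "family", "new")),
              fragmentRate >= 0, fragmentRate <= 1)
    if (bands$family[1] < 42 || bands$family[2] > 53 ||
        bands$new[2] > 38 || bands$subfamily[1] < 57)
        stop("identity bands must keep >= 2-point margins around 40 and 55")
    structure(list(seed = as.integer(seed), nGenomes = as.integer(nGenomes),
                   nFamilies = as.integer(nFamilies),
                   archetypeLength = as.integer(archetypeLength),
                   meanCopies = meanCopies, bands = bands,
                   bandWeights = bandWeights, fragmentRate = fragmentRate,
                   decoysPerGenome = as.integer(decoysPerGenome),
                   clustersPerGenome = as.integer(clustersPerGenome),
                   maxPerCluster = as.integer(maxPerCluster),
                   clusterSizeWeights = clusterSizeWeights,
                   bgcTypeWeights = bgcTypeWeights,
                   forceMaxCluster = isTRUE(forceMaxCluster)),
              class = "SimulationConfig")
}

# archetype with window-compliant EXXR and CXG; returns list(seq, frozen)
.makeArchetype <- function(L) {
    s <- sample(.AA20, L, replace = TRUE)
    e <- round(0.70 * L)
    cx <- L - 60L
    s[e:(e + 3L)] <- c("E", sample(setdiff(.AA20, c("E", "C")), 2,
                                   replace = TRUE), "R")
    s[cx:(cx + 2L)] <- c("C", sample(setdiff(.AA20, c("E", "C")), 1), "G")
    list(seq = paste(s, collapse = ""), frozen = c(e:(e + 3L), cx:(cx + 2L)),
         exxr = e, cxg = cx)
}

# BLOSUM62-weighted substitution at k non-frozen positions
.mutateSequence <- function(seq, k, frozen, blosum) {
    v <- strsplit(seq, "")[[1]]
    free <- setdiff(seq_along(v), frozen)
    pos <- sample(free, min(k, length(free)))
    for (p in pos) {
        orig <- v[p]
        cand <- setdiff(.AA20, orig)
        w <- exp(blosum[orig, cand] / 2)
        v[p] <- sample(cand, 1, prob = w)
    }
    paste(v, collapse = "")
}

#' Simulate a reference panel of archetype P450s
#'
#' Generates one archetype sequence per family, each carrying
#' window-compliant EXXR and CXG motifs, with all pairwise identities
#' below 40% (rejection-sampled). Families are named `CYP9001`, `CYP9002`,
#' ... with subfamily `A` and allele 1. Deterministic under the
#' configuration seed.
#'
#' @param config a [simulationConfig()].
#' @param maxTries rejection-sampling attempts per archetype.
#' @return a [ReferencePanel-class] with attribute `"archetypeInfo"` (frozen
#'   motif positions per family).
#' @export
simulatePanel <- function(config = simulationConfig(), maxTries = 25L) {
    set.seed(config$seed)
    params <- .defaultParams()
    seqs <- character(0)
    info <- list()
    for (i in seq_len(config$nFamilies)) {
        ok <- FALSE
        for (try in seq_len(maxTries)) {
            arch <- .makeArchetype(config$archetypeLength)
            ids <- vapply(seqs, function(s)
                pairwiseIdentity(arch$seq, s, params)$identity_pct,
                numeric(1))
            if (all(ids < 40)) { ok <- TRUE; break }
        }
        if (!ok)
            stop("could not satisfy mutual dissimilarity; use fewer ",
                 "families or longer archetypes")
        nm <- sprintf("CYP%dA1", 9000L + i)
        seqs[nm] <- arch$seq
        info[[nm]] <- arch[c("frozen", "exxr", "cxg")]
    }
    panel <- referencePanel(seqs)
    attr(panel, "archetypeInfo") <- info
    panel
}

# one planted complete P450 in a given identity band; measure-and-resample
.plantP450 <- function(arch, band, blosum, params, maxTries = 25L) {
    L <- nchar(arch$seq)
    lo <- band[1]; hi <- band[2]
    for (try in seq_len(maxTries)) {
        t <- runif(1, lo + 1, hi - 1)
        k <- round(L * (1 - t / 100))
        mut <- .mutateSequence(arch$seq, k, arch$frozen, blosum)
        meas <- pairwiseIdentity(mut, arch$seq, params)$identity_pct
        if (meas > lo && meas < hi)
            return(list(seq = mut, identity = meas))
    }
    stop("band calibration failed after ", maxTries, " tries for band (",
         lo, ",", hi, ")")
}

# fragment plants: motif ablation (EXXR only) or truncation (both, short)
.plantFragment <- function(arch, blosum, mode = c("ablate-cxg", "short")) {
    mode <- match.arg(mode)
    L <- nchar(arch$seq)
    mut <- .mutateSequence(arch$seq, round(0.15 * L), arch$frozen, blosum)
    v <- strsplit(mut, "")[[1]]
    if (mode == "ablate-cxg") {
        win <- max(1L, L - 119L):L
        v[win][v[win] == "C"] <- "S"
        paste(v, collapse = "")
    } else {
        shortLen <- 250L
        paste(v[(L - shortLen + 1L):L], collapse = "")
    }
}

# motif-free decoy (no E, no C anywhere)
.plantDecoy <- function(len = 300L) {
    paste(sample(setdiff(.AA20, c("E", "C")), len, replace = TRUE),
          collapse = "")
}

#' Simulate one genome with planted P450s, fragments and decoys
#'
#' Plants per-family P450 copies (Poisson counts) mutated away from the
#' family archetype into a sampled identity band -- calibration is by
#' measurement: mutants are re-aligned to the archetype and resampled until
#' the measured identity lies strictly inside the band -- plus P450
#' fragments (by heme-motif ablation or truncation below the length
#' threshold) and motif-free decoy proteins. Genes are laid out on one
#' synthetic contig with non-overlapping 1-based coordinates; the P450s
#' destined for one cluster occupy consecutive positions so cluster
#' intervals contain exactly their members.
#'
#' @param config a [simulationConfig()].
#' @param panel panel from [simulatePanel()].
#' @param genomeIndex genome number (1-based); also offsets the RNG seed.
#' @return a list with `records` (protein record `data.frame`), `truth`
#'   (per-protein `data.frame`: `id`, `type`, `family`, `band`,
#'   `identity_to_archetype`) and `clusterPlan` (list of member-id vectors,
#'   one per planned cluster).
#' @export
simulateGenome <- function(config, panel, genomeIndex) {
    set.seed(config$seed + 7919L * as.integer(genomeIndex))
    params <- .defaultParams()
    env <- new.env()
    utils::data(list = "BLOSUM62", package = "Biostrings", envir = env)
    blosum <- get("BLOSUM62", envir = env)
    info <- attr(panel, "archetypeInfo")
    gid <- sprintf("genome%02d", genomeIndex)
    fams <- names(panel)
    aseqs <- as.character(panelSequences(panel))

    proteins <- list()
    counter <- 0L
    nextId <- function() {
        counter <<- counter + 1L
        sprintf("%s_p%03d", gid, counter)
    }
    counts <- stats::rpois(length(fams), config$meanCopies)
    for (fi in seq_along(fams)) {
        arch <- c(list(seq = aseqs[fi]), info[[fams[fi]]])
        for (j in seq_len(counts[fi])) {
            band <- sample(names(config$bandWeights), 1,
                           prob = config$bandWeights)
            pl <- .plantP450(arch, config$bands[[band]], blosum, params)
            proteins[[length(proteins) + 1L]] <- list(
                id = nextId(), type = "P450",
                family = panelFamily(panel)[[fams[fi]]], band = band,
                identity = pl$identity, seq = pl$seq)
        }
    }
    nP450 <- length(proteins)
    nFrag <- stats::rpois(1, config$fragmentRate * max(nP450, 1))
    for (j in seq_len(nFrag)) {
        fi <- sample(seq_along(fams), 1)
        arch <- c(list(seq = aseqs[fi]), info[[fams[fi]]])
        mode <- sample(c("ablate-cxg", "short"), 1)
        proteins[[length(proteins) + 1L]] <- list(
            id = nextId(), type = "fragment",
            family = panelFamily(panel)[[fams[fi]]], band = mode,
            identity = NA_real_, seq = .plantFragment(arch, blosum, mode))
    }
    for (j in seq_len(config$decoysPerGenome)) {
        proteins[[length(proteins) + 1L]] <- list(
            id = nextId(), type = "decoy", family = NA_character_,
            band = NA_character_, identity = NA_real_, seq = .plantDecoy())
    }

    # cluster plan: distinct P450s, at least two left unclustered
    p450_ids <- vapply(proteins[seq_len(nP450)], `[[`, character(1), "id")
    plan <- list()
    avail <- sample(p450_ids)
    budget <- max(0L, nP450 - 2L)
    for (k in seq_len(config$clustersPerGenome)) {
        size <- if (k == 1 && genomeIndex == 1 && config$forceMaxCluster)
            config$maxPerCluster
        else
            sample(seq_len(config$maxPerCluster), 1,
                   prob = config$clusterSizeWeights)
        if (size > budget) {
            if (k == 1 && genomeIndex == 1 && config$forceMaxCluster)
                stop("requested cluster members exceed available P450s")
            next
        }
        plan[[length(plan) + 1L]] <- avail[seq_len(size)]
        avail <- avail[-seq_len(size)]
        budget <- budget - size
    }

    # layout: each cluster a contiguous block, everything else singleton
    ids <- vapply(proteins, `[[`, character(1), "id")
    clustered <- unlist(plan)
    blocks <- c(plan, as.list(setdiff(ids, clustered)))
    blocks <- blocks[sample(length(blocks))]
    order_ids <- unlist(blocks)
    pos <- 1L
    coords <- list()
    seqs <- setNames(vapply(proteins, `[[`, character(1), "seq"), ids)
    for (id in order_ids) {
        len_nt <- 3L * nchar(seqs[[id]])
        coords[[id]] <- c(pos, pos + len_nt - 1L)
        pos <- pos + len_nt + 200L
    }
    records <- data.frame(
        id = order_ids, genome_id = gid, contig_id = "ctg1",
        start = vapply(order_ids, function(i) coords[[i]][1], integer(1)),
        end = vapply(order_ids, function(i) coords[[i]][2], integer(1)),
        strand = sample(c("+", "-"), length(order_ids), replace = TRUE),
        sequence = unname(seqs[order_ids]), stringsAsFactors = FALSE)
    rownames(records) <- NULL
    truth <- data.frame(
        id = ids, genome_id = gid,
        type = vapply(proteins, `[[`, character(1), "type"),
        family = vapply(proteins, `[[`, character(1), "family"),
        band = vapply(proteins, `[[`, character(1), "band"),
        identity_to_archetype = vapply(proteins, `[[`, numeric(1),
                                       "identity"),
        stringsAsFactors = FALSE)
    list(records = records, truth = truth, clusterPlan = plan)
}

#' Simulate the smBGC interval table for simulated genomes
#'
#' Turns each genome's planned cluster blocks into typed intervals spanning
#' the member genes plus a margin smaller than the intergenic gap, so full
#' containment holds for exactly the planted members. Types are sampled
#' from the configured type-frequency table.
#'
#' @param config a [simulationConfig()].
#' @param genomes list of [simulateGenome()] results.
#' @return a list with `clusters` (cluster table `data.frame`) and
#'   `membership` (`data.frame` of `cluster_id`, `gene_id` ground truth).
#' @export
simulateBgcTable <- function(config, genomes) {
    set.seed(config$seed + 104729L)
    rows <- list()
    memb <- list()
    for (g in genomes) {
        gid <- g$records$genome_id[1]
        for (k in seq_along(g$clusterPlan)) {
            members <- g$clusterPlan[[k]]
            if (length(members) > nrow(g$records))
                stop("requested cluster members exceed available P450s")
            r <- g$records[g$records$id %in% members, , drop = FALSE]
            cid <- sprintf("%s_bgc%02d", gid, k)
            rows[[length(rows) + 1L]] <- data.frame(
                genome_id = gid, contig_id = "ctg1", cluster_id = cid,
                bgc_type = sample(names(config$bgcTypeWeights), 1,
                                  prob = config$bgcTypeWeights),
                start = max(1L, min(r$start) - 100L),
                end = max(r$end) + 100L, stringsAsFactors = FALSE)
            memb[[length(memb) + 1L]] <- data.frame(
                cluster_id = cid, gene_id = members,
                stringsAsFactors = FALSE)
        }
    }
    clusters <- if (length(rows)) do.call(rbind, rows) else
        data.frame(genome_id = character(), contig_id = character(),
                   cluster_id = character(), bgc_type = character(),
                   start = integer(), end = integer(),
                   stringsAsFactors = FALSE)
    membership <- if (length(memb)) do.call(rbind, memb) else
        data.frame(cluster_id = character(), gene_id = character(),
                   stringsAsFactors = FALSE)
    list(clusters = clusters, membership = membership)
}

#' Simulate a complete synthetic CYPome study
#'
#' Convenience wrapper running [simulatePanel()], [simulateGenome()] for
#' every genome and [simulateBgcTable()], optionally writing all artifacts
#' (panel FASTA, per-genome protein FASTA, gene table TSV, cluster TSV,
#' ground-truth JSON) to a directory in the same formats the pipeline
#' consumes. Byte-identical outputs for identical configurations.
#'
#' @param config a [simulationConfig()].
#' @param dir optional output directory.
#' @return a list with `panel`, `records` (all genomes combined), `truth`,
#'   `clusters`, `membership`, and (when `dir` is given) `paths`.
#' @examples
#' cfg <- simulationConfig(seed = 7, nGenomes = 2, nFamilies = 3,
#'                         meanCopies = 1.5, clustersPerGenome = 1,
#'                         maxPerCluster = 2,
#'                         clusterSizeWeights = c(0.5, 0.5),
#'                         forceMaxCluster = FALSE)
#' sim <- simulateCypome(cfg)
#' table(sim$truth$type)
#' @export
simulateCypome <- function(config = simulationConfig(), dir = NULL) {
    panel <- simulatePanel(config)
    genomes <- lapply(seq_len(config$nGenomes), function(i)
        simulateGenome(config, panel, i))
    bgc <- simulateBgcTable(config, genomes)
    records <- do.call(rbind, lapply(genomes, `[[`, "records"))
    truth <- do.call(rbind, lapply(genomes, `[[`, "truth"))
    rownames(records) <- rownames(truth) <- NULL
    out <- list(panel = panel, records = records, truth = truth,
                clusters = bgc$clusters, membership = bgc$membership)
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        paths <- list(panel = file.path(dir, "panel.faa"),
                      genes = file.path(dir, "genes.tsv"),
                      clusters = file.path(dir, "clusters.tsv"),
                      truth = file.path(dir, "ground_truth.json"))
        writeReferencePanel(panel, paths$panel)
        for (g in genomes) {
            gid <- g$records$genome_id[1]
            p <- file.path(dir, paste0(gid, ".faa"))
            writeProteinFasta(g$records, p)
            paths[[gid]] <- p
        }
        gt <- records[, c("genome_id", "contig_id", "id", "start", "end",
                          "strand")]
        names(gt)[3] <- "gene_id"
        writeGeneTable(gt, paths$genes)
        writeBgcTable(bgc$clusters, paths$clusters)
        jsonlite::write_json(list(proteins = truth,
                                  membership = bgc$membership),
                             paths$truth, dataframe = "columns",
                             digits = NA)
        out$paths <- paths
    }
    out
}
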