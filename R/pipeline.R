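#' Run the CYPome mining pipeline end to end
#'
#' Chains every stage over protein FASTA input: optional domain-hit
#' pre-filter, motif classification, family/subfamily assignment against a
#' reference panel, genome-by-family profiling, summary statistics,
#' presence/absence heat-map clustering, smBGC linkage (when a cluster
#' table is given) and a neighbor-joining tree over per-family
#' representatives. All artifacts are written to `outDir` together with a
#' manifest of parameters and input checksums; re-running with identical
#' inputs reproduces identical data outputs.
#'
#' @param proteinFiles character vector of protein FASTA paths (one or more
#'   genomes).
#' @param panelFile reference panel FASTA path.
#' @param outDir output directory (created if needed).
#' @param clusterFile optional smBGC interval TSV.
#' @param domainHitsFile optional domain-hit TSV (`protein_id`,
#'   `has_ipr001128`).
#' @param config a [motifConfig()].
#' @param params an [alignmentParams()].
#' @param familyThreshold,subfamilyThreshold nomenclature thresholds.
#' @param overlap cluster membership by any-overlap instead of containment.
#' @param treeMaxPerFamily representatives per family for the tree stage
#'   (all-pairs alignment is quadratic); `0` skips the tree.
#' @return invisibly, a list with the in-memory stage results (`calls`,
#'   `assignments`, `profile`, `stats`, `heatmap`, `linkage`, `aggregates`,
#'   `tree`) and `outDir`.
#' @export
runPipeline <- function(proteinFiles, panelFile, outDir,
                        clusterFile = NULL, domainHitsFile = NULL,
                        config = motifConfig(),
                        params = .defaultParams(),
                        familyThreshold = 40, subfamilyThreshold = 55,
                        overlap = FALSE, treeMaxPerFamily = 8L) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    records <- do.call(rbind, lapply(proteinFiles, readProteinFasta))
    panel <- readReferencePanel(panelFile)
    if (!is.null(domainHitsFile)) {
        hits <- read.delim(domainHitsFile, stringsAsFactors = FALSE)
        records <- applyDomainPrefilter(records, hits)
    }
    calls <- classifyProteins(records, config)
    assignments <- assignFamilies(calls, panel, params, familyThreshold,
                                  subfamilyThreshold)
    writeAssignmentTable(assignments, file.path(outDir, "assignments.tsv"))
    profile <- buildProfile(assignments, calls)
    writeProfileTable(profile, file.path(outDir, "profile.tsv"))

    linkage <- NULL
    aggregates <- NULL
    nInBgc <- NA_integer_
    if (!is.null(clusterFile)) {
        clusters <- readBgcTable(clusterFile)
        genes <- p450GeneTable(calls, assignments)
        linkage <- assignP450sToClusters(genes, clusters, overlap = overlap)
        aggregates <- aggregateByType(linkage$signatures)
        nInBgc <- nrow(linkage$memberships)
        writeSignatureTable(linkage$signatures,
                            file.path(outDir, "signatures.tsv"))
        writeTypeAggregateTable(aggregates,
                                file.path(outDir, "type_aggregates.tsv"))
    }

    nSub <- nrow(unique(assignments[, c("family", "subfamily")]))
    stats <- computeStats(profile, nSubfamilies = nSub, nInBgc = nInBgc)
    jsonlite::write_json(
        list(raw = unclass(stats), reported = unclass(formatStats(stats))),
        file.path(outDir, "stats.json"), auto_unbox = TRUE, digits = NA)

    heatmap <- NULL
    if (nrow(profileCounts(profile)) >= 2 && ncol(profileCounts(profile)) >= 2) {
        heatmap <- clusterHeatmap(profile)
        writeHeatmapTable(heatmap, file.path(outDir, "heatmap.tsv"))
    }

    tree <- NULL
    if (treeMaxPerFamily > 0 && nrow(assignments) >= 3) {
        reps <- unlist(lapply(split(assignments$query_id,
                                    assignments$family), function(ids)
            utils::head(sort(ids), treeMaxPerFamily)))
        sub <- calls[match(reps, calls$id), ]
        if (nrow(sub) >= 3) {
            dm <- buildDistanceMatrix(setNames(sub$sequence, sub$id), params)
            tree <- njTree(dm)
            writeNewickTree(tree, file.path(outDir, "tree.nwk"))
            ann <- familyColoring(tree, assignments)
            write.table(ann, file.path(outDir, "tree_annotation.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        }
    }

    inputs <- c(proteinFiles, panelFile, clusterFile, domainHitsFile)
    manifest <- list(
        package = "cypome",
        version = as.character(packageVersion("cypome")),
        parameters = list(minLength = config$minLength,
                          useWindows = config$useWindows,
                          familyThreshold = familyThreshold,
                          subfamilyThreshold = subfamilyThreshold,
                          gapOpening = params$gapOpening,
                          gapExtension = params$gapExtension,
                          overlap = overlap,
                          treeMaxPerFamily = treeMaxPerFamily),
        inputs = as.list(tools::md5sum(inputs)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(list(calls = calls, assignments = assignments,
                   profile = profile, stats = stats, heatmap = heatmap,
                   linkage = linkage, aggregates = aggregates, tree = tree,
                   outDir = outDir))
}

#' Recompute the published-style summary from the packaged fixtures
#'
#' Fixtures-only mode: reproduces the headline CYPome quantities from the
#' packaged table transcriptions alone, with no sequence input -- strain
#' totals from the per-strain table, family totals from the family table,
#' and smBGC aggregates from the cluster-composition table.
#'
#' @param fixtures result of [loadFixtureTables()].
#' @return a list with `stats` (a [cypomeStats()] object), `aggregates`
#'   (from [aggregateByType()] over the expanded fixture signatures),
#'   `breakdown` (from [bgcFamilyBreakdown()]), `familyCounts` (named
#'   vector of per-family totals) and `maxPerStrain`.
#' @export
fixtureReport <- function(fixtures = loadFixtureTables()) {
    t2 <- fixtures$table2
    t3 <- fixtures$table3
    famtab <- t3[!duplicated(t3$family), ]
    familyCounts <- setNames(famtab$family_count, famtab$family)
    sigs <- fixtureSignatures(fixtures$table4)
    aggregates <- aggregateByType(sigs)
    stats <- cypomeStats(
        nP450 = sum(t2$n_p450), nSpecies = nrow(t2),
        nSpeciesWithP450 = sum(t2$n_p450 > 0),
        nFamilies = length(unique(t3$family)),
        nSubfamilies = nrow(t3),
        nInBgc = sum(aggregates$types$n_p450_total))
    list(stats = stats, aggregates = aggregates,
         breakdown = bgcFamilyBreakdown(sigs),
         familyCounts = familyCounts,
         maxPerStrain = max(t2$n_p450),
         fragments = sum(t2$n_fragments))
}

#' Key-feature report column
#'
#' Assembles the 13-row key-feature summary (species counts, P450, family
#' and subfamily totals, dominant family, average, diversity percentage
#' and smBGC linkage figures) in report rounding.
#'
#' @param stats a [cypomeStats()] object.
#' @param familyCounts named vector of per-family P450 totals.
#' @param breakdown result of [bgcFamilyBreakdown()].
#' @return a named list of the 13 report rows.
#' @export
reportTable1Column <- function(stats, familyCounts, breakdown) {
    f <- formatStats(stats)
    list(
        "Species analysed" = stats$n_species,
        "Species without P450s" = stats$n_species - stats$n_species_with_p450,
        "Species with P450s" = stats$n_species_with_p450,
        "Percentage of species with P450s" =
            round(100 * stats$n_species_with_p450 / stats$n_species),
        "No. of P450s" = stats$n_p450,
        "No. of families" = stats$n_families,
        "No. of subfamilies" = stats$n_subfamilies,
        "Dominant P450 family" =
            names(familyCounts)[which.max(familyCounts)],
        "Average No. of P450s" = f$avg_p450,
        "P450 diversity percentage" = f$diversity_pct,
        "No. of P450s part of BGCs" = stats$n_in_bgc,
        "No. of P450 families part of BGCs" = nrow(breakdown),
        "Percentage of P450s part of BGCs" = f$pct_in_bgc)
}
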