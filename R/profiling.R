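#' Build the genome-by-family CYPome profile
#'
#' Counts complete P450s per genome and family from the assignment table,
#' and fragments per genome from the classified calls. Genomes with no
#' P450s keep an all-zero row; genome order and family order are sorted for
#' determinism.
#'
#' @param assignments assignment table from [assignFamilies()]; must cover
#'   every `status == "P450"` call.
#' @param calls classified records from [classifyProteins()].
#' @return a [CypomeProfile-class].
#' @export
buildProfile <- function(assignments, calls) {
    p450 <- calls[calls$status == "P450", , drop = FALSE]
    if (!all(assignments$query_id %in% p450$id))
        stop("assignment for unknown call: ",
             paste(setdiff(assignments$query_id, p450$id), collapse = ", "))
    if (!all(p450$id %in% assignments$query_id))
        stop("assignments must cover every complete P450 call")
    genomes <- sort(unique(calls$genome_id))
    families <- sort(unique(assignments$family))
    counts <- matrix(0L, length(genomes), length(families),
                     dimnames = list(genomes, families))
    if (nrow(assignments)) {
        tab <- table(factor(assignments$genome_id, levels = genomes),
                     factor(assignments$family, levels = families))
        counts[] <- as.integer(tab)
    }
    frag <- calls[calls$status == "fragment", , drop = FALSE]
    fragments <- as.integer(table(factor(frag$genome_id, levels = genomes)))
    names(fragments) <- genomes
    new("CypomeProfile", counts = counts, fragments = fragments)
}

#' CYPome summary statistics
#'
#' Closed-form summary statistics over a CYPome:
#' \itemize{
#'   \item average number of P450s = number of P450s / number of species;
#'   \item P450 diversity percentage = 100 x number of P450 families /
#'     (number of P450s x number of species with P450s);
#'   \item percentage of P450s part of BGCs = 100 x number of P450s part of
#'     BGCs / total number of P450s.
#' }
#' Raw real values are retained; [formatStats()] applies report rounding
#' (average and BGC percentage to integers, diversity to 2 decimals).
#'
#' @param nP450 total number of complete P450s.
#' @param nSpecies number of species (genomes) analysed.
#' @param nSpeciesWithP450 number of species carrying at least one P450.
#' @param nFamilies,nSubfamilies family and subfamily totals.
#' @param nInBgc number of P450s inside smBGCs (NA when unknown).
#' @return a list of class `SummaryStats` with the inputs plus `avg_p450`,
#'   `diversity_pct`, `pct_in_bgc`.
#' @examples
#' s <- cypomeStats(2643, 126, 126, 45, 103, 1236)
#' formatStats(s)$avg_p450      # 21
#' formatStats(s)$diversity_pct # 0.01
#' formatStats(s)$pct_in_bgc    # 47
#' @export
cypomeStats <- function(nP450, nSpecies, nSpeciesWithP450, nFamilies,
                        nSubfamilies, nInBgc = NA_integer_) {
    if (nSpecies <= 0) stop("average undefined for zero species")
    avg <- nP450 / nSpecies
    if (nP450 <= 0 || nSpeciesWithP450 <= 0)
        stop("diversity undefined for zero P450s or zero species with P450s")
    div <- 100 * nFamilies / (nP450 * nSpeciesWithP450)
    pct_bgc <- if (is.na(nInBgc)) NA_real_ else 100 * nInBgc / nP450
    structure(list(n_species = nSpecies,
                   n_species_with_p450 = nSpeciesWithP450,
                   n_p450 = nP450, n_families = nFamilies,
                   n_subfamilies = nSubfamilies,
                   avg_p450 = avg, diversity_pct = div,
                   n_in_bgc = nInBgc, pct_in_bgc = pct_bgc),
              class = "SummaryStats")
}

#' @rdname cypomeStats
#' @param profile a [CypomeProfile-class].
#' @param nSubfamilies number of subfamilies (known from the assignment
#'   table, not the family-level profile).
#' @param nInBgc number of P450s inside smBGCs.
#' @export
computeStats <- function(profile, nSubfamilies, nInBgc = NA_integer_) {
    m <- profileCounts(profile)
    cypomeStats(nP450 = sum(m), nSpecies = nrow(m),
                nSpeciesWithP450 = sum(rowSums(m) > 0),
                nFamilies = ncol(m), nSubfamilies = nSubfamilies,
                nInBgc = nInBgc)
}

#' @rdname cypomeStats
#' @param stats a `SummaryStats` list.
#' @export
formatStats <- function(stats) {
    out <- stats
    out$avg_p450 <- round(stats$avg_p450)
    out$diversity_pct <- round(stats$diversity_pct, 2)
    if (!is.na(stats$pct_in_bgc)) out$pct_in_bgc <- round(stats$pct_in_bgc)
    out
}

#' Detect bloomed P450 families
#'
#' A family is called bloomed when it recurs in multiple copies within
#' individual genomes: count >= `multiCopyMin` in at least a fraction
#' `genomeFracMin` of genomes.
#'
#' @param profile a [CypomeProfile-class].
#' @param multiCopyMin per-genome copy number defining "multi-copy"
#'   (default 3).
#' @param genomeFracMin minimum fraction of genomes (default 0.5).
#' @return character vector of bloomed family names.
#' @export
detectBloomed <- function(profile, multiCopyMin = 3L, genomeFracMin = 0.5) {
    m <- profileCounts(profile)
    frac <- colMeans(m >= multiCopyMin)
    colnames(m)[frac >= genomeFracMin]
}

#' Detect conserved P450 families
#'
#' A family is conserved when present (count >= 1) in at least a fraction
#' `presenceFracMin` of genomes (default 1, i.e. every genome).
#'
#' @param profile a [CypomeProfile-class].
#' @param presenceFracMin minimum presence fraction (default 1.0).
#' @return character vector of conserved family names.
#' @export
detectConserved <- function(profile, presenceFracMin = 1.0) {
    m <- profileCounts(profile)
    frac <- colMeans(m > 0)
    colnames(m)[frac >= presenceFracMin]
}

#' Cluster the presence/absence heat-map
#'
#' Encodes the profile as 3 (family present) / -3 (family absent) and
#' hierarchically clusters rows (genomes) and columns (families) with
#' Euclidean distance and average linkage, as done for published CYPome
#' profile heat-maps. Output is deterministic given the input order.
#'
#' @param profile a [CypomeProfile-class] with >= 2 genomes and >= 2
#'   families.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default "average").
#' @return a [CypomeHeatmap-class]. For a degenerate all-equal matrix the
#'   identity permutations are returned with a warning.
#' @export
clusterHeatmap <- function(profile, linkage = "average") {
    m <- profileCounts(profile)
    if (nrow(m) < 2 || ncol(m) < 2)
        stop("heat-map clustering needs >= 2 genomes and >= 2 families")
    enc <- ifelse(m > 0, 3, -3)
    dimnames(enc) <- dimnames(m)
    if (length(unique(as.vector(enc))) == 1) {
        warning("degenerate all-equal matrix; identity ordering returned")
        return(new("CypomeHeatmap", values = enc,
                   rowOrder = seq_len(nrow(enc)),
                   colOrder = seq_len(ncol(enc)),
                   rowDendro = NULL, colDendro = NULL))
    }
    hr <- hclust(dist(enc, method = "euclidean"), method = linkage)
    hc <- hclust(dist(t(enc), method = "euclidean"), method = linkage)
    new("CypomeHeatmap", values = enc,
        rowOrder = as.integer(hr$order), colOrder = as.integer(hc$order),
        rowDendro = hr, colDendro = hc)
}

#' Write profile and heat-map exports
#'
#' `writeProfileTable()` writes the genome x family count matrix as TSV;
#' `writeHeatmapTable()` writes the -3/3 matrix in clustered order with the
#' permutations recorded in comment header lines.
#'
#' @param profile a [CypomeProfile-class].
#' @param heatmap a [CypomeHeatmap-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeProfileTable <- function(profile, path) {
    m <- profileCounts(profile)
    df <- data.frame(genome_id = rownames(m), m, fragments =
                     fragmentCounts(profile), check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeProfileTable
#' @export
writeHeatmapTable <- function(heatmap, path) {
    v <- heatmapValues(heatmap)[heatmapRowOrder(heatmap),
                                heatmapColOrder(heatmap), drop = FALSE]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("# row_order\t",
                        paste(heatmapRowOrder(heatmap), collapse = ",")),
                 paste0("# col_order\t",
                        paste(heatmapColOrder(heatmap), collapse = ","))), con)
    write.table(data.frame(genome_id = rownames(v), v, check.names = FALSE),
                con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
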