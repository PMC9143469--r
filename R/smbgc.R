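#' Read an smBGC interval table
#'
#' Cluster tables carry one typed genomic interval per row: `genome_id`,
#' `contig_id`, `cluster_id`, `bgc_type`, `start`, `end` (1-based
#' inclusive). The type vocabulary is open (antiSMASH-style labels such as
#' T1PKS, NRPS, bacteriocin, indole, terpene, ...); unknown types pass
#' through.
#'
#' @param path TSV file path.
#' @return a `data.frame` with the columns above.
#' @export
readBgcTable <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("genome_id", "contig_id", "cluster_id", "bgc_type", "start",
              "end")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("cluster table ", path, " lacks columns: ",
             paste(miss, collapse = ", "))
    if (any(tab$start > tab$end)) stop("cluster table has start > end rows")
    if (anyDuplicated(tab[, c("genome_id", "cluster_id")]))
        stop("duplicate (genome_id, cluster_id) pairs in ", path)
    tab[need]
}

#' @rdname readBgcTable
#' @param table cluster table `data.frame`.
#' @export
writeBgcTable <- function(table, path) {
    write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Build the P450 gene table for cluster linkage
#'
#' Joins classified calls with their family assignments into the gene
#' table [assignP450sToClusters()] consumes. Labels are family+subfamily
#' (e.g. `CYP105AB`); placeholder subfamilies (`!1`, ...) are dropped from
#' the label, leaving the family alone.
#'
#' @param calls classified records from [classifyProteins()].
#' @param assignments assignment table from [assignFamilies()].
#' @return a `data.frame` with `gene_id`, `genome_id`, `contig_id`,
#'   `start`, `end`, `label` for every complete P450.
#' @export
p450GeneTable <- function(calls, assignments) {
    genes <- merge(
        calls[calls$status == "P450",
              c("id", "genome_id", "contig_id", "start", "end")],
        assignments[, c("query_id", "family", "subfamily")],
        by.x = "id", by.y = "query_id")
    genes$label <- paste0(
        genes$family,
        ifelse(is.na(genes$subfamily) | startsWith(genes$subfamily, "!"),
               "", genes$subfamily))
    names(genes)[names(genes) == "id"] <- "gene_id"
    genes[, c("gene_id", "genome_id", "contig_id", "start", "end", "label")]
}

#' Assign P450 genes to smBGC intervals
#'
#' A P450 gene is a member of a cluster when it lies on the same genome and
#' contig and its `[start, end]` interval is fully contained in the
#' cluster's (the default; set `overlap = TRUE` to accept any overlap).
#' Members are ordered by start coordinate, so each cluster's composition
#' signature (comma-joined family+subfamily labels) preserves gene order
#' along the contig. A gene contained in several overlapping clusters is
#' recorded in each, with a warning.
#'
#' @param genes `data.frame` of P450 genes with columns `gene_id`,
#'   `genome_id`, `contig_id`, `start`, `end`, `label` (family+subfamily,
#'   e.g. `CYP105AB`). Typically built by merging [classifyProteins()]
#'   output with [assignFamilies()] labels.
#' @param clusters cluster table (see [readBgcTable()]).
#' @param overlap logical; membership by any overlap instead of full
#'   containment.
#' @return a list with `signatures` (one row per cluster: `cluster_id`,
#'   `genome_id`, `bgc_type`, `signature`, `n_p450`), `memberships`
#'   (gene-to-cluster rows in coordinate order) and `residual` (ids of
#'   P450 genes in no cluster).
#' @export
assignP450sToClusters <- function(genes, clusters, overlap = FALSE) {
    stopifnot(all(c("gene_id", "genome_id", "contig_id", "start", "end",
                    "label") %in% names(genes)))
    memb <- list()
    for (i in seq_len(nrow(clusters))) {
        cl <- clusters[i, ]
        g <- genes[genes$genome_id == cl$genome_id &
                   genes$contig_id == cl$contig_id, , drop = FALSE]
        hit <- if (overlap)
            g$start <= cl$end & g$end >= cl$start
        else
            g$start >= cl$start & g$end <= cl$end
        g <- g[hit, , drop = FALSE]
        if (nrow(g)) {
            g <- g[order(g$start, g$gene_id), , drop = FALSE]
            memb[[length(memb) + 1L]] <- data.frame(
                cluster_id = cl$cluster_id, genome_id = cl$genome_id,
                bgc_type = cl$bgc_type, gene_id = g$gene_id,
                label = g$label, start = g$start,
                stringsAsFactors = FALSE)
        }
    }
    memberships <- if (length(memb)) do.call(rbind, memb) else
        data.frame(cluster_id = character(), genome_id = character(),
                   bgc_type = character(), gene_id = character(),
                   label = character(), start = integer(),
                   stringsAsFactors = FALSE)
    multi <- unique(memberships$gene_id[duplicated(memberships$gene_id)])
    if (length(multi))
        warning("genes contained in multiple overlapping clusters: ",
                paste(multi, collapse = ", "))
    sigs <- lapply(seq_len(nrow(clusters)), function(i) {
        cl <- clusters[i, ]
        rows <- memberships[memberships$cluster_id == cl$cluster_id &
                            memberships$genome_id == cl$genome_id, ,
                            drop = FALSE]
        data.frame(cluster_id = cl$cluster_id, genome_id = cl$genome_id,
                   bgc_type = cl$bgc_type,
                   signature = paste(rows$label, collapse = ","),
                   n_p450 = nrow(rows), stringsAsFactors = FALSE)
    })
    signatures <- do.call(rbind, sigs)
    if (is.null(signatures))
        signatures <- data.frame(cluster_id = character(),
                                 genome_id = character(),
                                 bgc_type = character(),
                                 signature = character(), n_p450 = integer(),
                                 stringsAsFactors = FALSE)
    list(signatures = signatures, memberships = memberships,
         residual = setdiff(genes$gene_id, memberships$gene_id))
}

#' Aggregate cluster signatures by smBGC type
#'
#' Groups P450-containing cluster signatures by type and tallies, per type,
#' the number of clusters, the distinct ordered composition varieties with
#' their cluster counts, and the total number of member P450s.
#'
#' @param signatures signature `data.frame` (from
#'   [assignP450sToClusters()] or [fixtureSignatures()]); clusters with
#'   `n_p450 == 0` are excluded from aggregation.
#' @return a list with `types` (one row per type: `bgc_type`, `n_clusters`,
#'   `n_varieties`, `n_p450_total`) and `varieties` (one row per type x
#'   signature: `bgc_type`, `signature`, `n_clusters`, `n_p450`).
#' @export
aggregateByType <- function(signatures) {
    s <- signatures[signatures$n_p450 > 0, , drop = FALSE]
    if (nrow(s) == 0)
        return(list(types = data.frame(bgc_type = character(),
                                       n_clusters = integer(),
                                       n_varieties = integer(),
                                       n_p450_total = integer(),
                                       stringsAsFactors = FALSE),
                    varieties = data.frame(bgc_type = character(),
                                           signature = character(),
                                           n_clusters = integer(),
                                           n_p450 = integer(),
                                           stringsAsFactors = FALSE)))
    key <- paste(s$bgc_type, s$signature, sep = "\r")
    ukey <- unique(key)
    varieties <- do.call(rbind, lapply(ukey, function(k) {
        rows <- s[key == k, , drop = FALSE]
        data.frame(bgc_type = rows$bgc_type[1], signature = rows$signature[1],
                   n_clusters = nrow(rows), n_p450 = sum(rows$n_p450),
                   stringsAsFactors = FALSE)
    }))
    types <- do.call(rbind, lapply(unique(s$bgc_type), function(tp) {
        v <- varieties[varieties$bgc_type == tp, , drop = FALSE]
        data.frame(bgc_type = tp, n_clusters = sum(v$n_clusters),
                   n_varieties = nrow(v), n_p450_total = sum(v$n_p450),
                   stringsAsFactors = FALSE)
    }))
    rownames(types) <- rownames(varieties) <- NULL
    list(types = types, varieties = varieties)
}

#' Expand the packaged smBGC fixture into cluster signatures
#'
#' Each fixture row (type, variety count, ordered P450 composition) is
#' expanded into that many identical cluster signatures so the aggregation
#' operations can be run unchanged over the published table. Labels with a
#' literal `-fragment` suffix are dropped unless `includeFragments = TRUE`
#' (the pipeline itself never places fragments in signatures; the flag
#' restores fixture parity).
#'
#' @param table4 the `table4` element of [loadFixtureTables()].
#' @param includeFragments keep `-fragment`-suffixed labels (default TRUE,
#'   reproducing the printed table verbatim).
#' @return a signature `data.frame` as returned by
#'   [assignP450sToClusters()].
#' @export
fixtureSignatures <- function(table4, includeFragments = TRUE) {
    rows <- list()
    k <- 0L
    for (i in seq_len(nrow(table4))) {
        r <- table4[i, ]
        labels <- trimws(strsplit(r$p450_list, ",")[[1]])
        if (!includeFragments) {
            labels <- labels[!grepl("-fragment", labels)]
            if (length(labels) == 0) next
        }
        sig <- paste(labels, collapse = ",")
        for (j in seq_len(r$variety_count)) {
            k <- k + 1L
            rows[[k]] <- data.frame(
                cluster_id = sprintf("fixture_%04d", k),
                genome_id = "fixture", bgc_type = r$bgc_type,
                signature = sig, n_p450 = length(labels),
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

#' Maximum number of P450s in any single cluster
#'
#' @param signatures non-empty signature `data.frame`.
#' @return integer maximum of `n_p450`.
#' @export
maxP450sPerCluster <- function(signatures) {
    if (nrow(signatures) == 0) stop("no cluster signatures")
    max(signatures$n_p450)
}

#' Family breakdown of cluster-member P450s
#'
#' Extracts the family (leading `CYP`+digits) from every member label over
#' all P450-containing clusters and tallies counts and percentages of the
#' total cluster-member P450s.
#'
#' @param signatures signature `data.frame`.
#' @return a `data.frame` with `family`, `count`, `pct` (raw) sorted by
#'   decreasing count; percentages round to 0 decimals at report time.
#' @export
bgcFamilyBreakdown <- function(signatures) {
    s <- signatures[signatures$n_p450 > 0, , drop = FALSE]
    if (nrow(s) == 0)
        return(data.frame(family = character(), count = integer(),
                          pct = numeric(), stringsAsFactors = FALSE))
    labels <- unlist(lapply(s$signature, function(x)
        trimws(strsplit(x, ",")[[1]])))
    m <- regexpr(.FAMILY_RE, labels)
    if (any(m == -1))
        stop("label does not match the CYP family grammar: ",
             paste(unique(labels[m == -1]), collapse = ", "))
    fams <- regmatches(labels, m)
    tab <- sort(table(fams), decreasing = TRUE)
    data.frame(family = names(tab), count = as.integer(tab),
               pct = 100 * as.integer(tab) / length(fams),
               stringsAsFactors = FALSE)
}

#' Write signature and type-aggregate TSVs
#'
#' @param signatures signature `data.frame`.
#' @param aggregates result of [aggregateByType()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeSignatureTable <- function(signatures, path) {
    write.table(signatures, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' @rdname writeSignatureTable
#' @export
writeTypeAggregateTable <- function(aggregates, path) {
    v <- aggregates$varieties
    t <- aggregates$types
    v$type_count <- t$n_clusters[match(v$bgc_type, t$bgc_type)]
    out <- v[, c("bgc_type", "type_count", "n_clusters", "signature",
                 "n_p450")]
    names(out) <- c("bgc_type", "type_count", "variety_count", "p450_list",
                    "p450_count")
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
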