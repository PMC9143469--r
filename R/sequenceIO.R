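#' Read protein records from FASTA
#'
#' Reads a protein FASTA file into the canonical record table used by every
#' downstream stage. Header metadata is parsed from `key=value` tokens after
#' the record id (`genome`, `contig`, `start`, `end`, `strand`); unknown
#' tokens are ignored. Missing fields are defaulted: `genome_id` from the
#' file name (without extension), `contig_id` to `"unplaced"`, coordinates to
#' `1..length` (the sequence length) on strand `+`. Residues are uppercased.
#'
#' @param path path to a protein FASTA file.
#' @param genomeId default genome id for records whose header carries none;
#'   defaults to the file name without extension.
#' @return a `data.frame` with columns `id`, `genome_id`, `contig_id`,
#'   `start`, `end`, `strand`, `sequence` (one row per FASTA entry; zero rows
#'   for an empty file).
#' @examples
#' f <- tempfile(fileext = ".faa")
#' writeLines(c(">g1 genome=G contig=c1 start=10 end=39 strand=+",
#'              "MAEELLRAGT"), f)
#' readProteinFasta(f)
#' @export
readProteinFasta <- function(path, genomeId = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    if (is.null(genomeId))
        genomeId <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path)
    if (length(lines) == 0 || all(!nzchar(trimws(lines))))
        return(.emptyRecords())
    hdr_idx <- grep("^>", lines)
    if (length(hdr_idx) == 0 || hdr_idx[1] != 1)
        stop("malformed FASTA: expected '>' header at line 1 of ", path)
    ends <- c(hdr_idx[-1] - 1L, length(lines))
    recs <- lapply(seq_along(hdr_idx), function(i) {
        hdr <- sub("^>", "", lines[hdr_idx[i]])
        body <- if (ends[i] >= hdr_idx[i] + 1L)
            lines[(hdr_idx[i] + 1L):ends[i]] else character()
        seq <- toupper(gsub("[[:space:]]", "", paste(body, collapse = "")))
        if (!nzchar(seq))
            stop("malformed FASTA: empty sequence for header at line ",
                 hdr_idx[i], " of ", path)
        if (grepl("[^A-Z]", seq))
            stop("malformed FASTA: non-letter residue in record starting at line ",
                 hdr_idx[i], " of ", path)
        toks <- strsplit(trimws(hdr), "[[:space:]]+")[[1]]
        id <- toks[1]
        kv <- toks[-1][grepl("=", toks[-1])]
        keys <- sub("=.*$", "", kv)
        vals <- sub("^[^=]*=", "", kv)
        getv <- function(k, default) if (k %in% keys) vals[match(k, keys)] else default
        len <- nchar(seq)
        start <- suppressWarnings(as.integer(getv("start", NA)))
        end <- suppressWarnings(as.integer(getv("end", NA)))
        if (is.na(start)) start <- 1L
        if (is.na(end)) end <- start + len - 1L
        data.frame(
            id = id,
            genome_id = getv("genome", genomeId),
            contig_id = getv("contig", "unplaced"),
            start = start, end = end,
            strand = getv("strand", "+"),
            sequence = seq,
            stringsAsFactors = FALSE
        )
    })
    out <- do.call(rbind, recs)
    dup <- duplicated(out[, c("genome_id", "id")])
    if (any(dup))
        stop("duplicate record id within a genome: ",
             paste(out$id[dup], collapse = ", "))
    rownames(out) <- NULL
    out
}

.emptyRecords <- function() {
    data.frame(id = character(), genome_id = character(),
               contig_id = character(), start = integer(), end = integer(),
               strand = character(), sequence = character(),
               stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' Inverse of [readProteinFasta()]: headers carry the `key=value` metadata
#' tokens so that a write/read round trip reproduces the records.
#'
#' @param records protein record `data.frame` (see [readProteinFasta()]).
#' @param path output file path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(records, path, width = 60L) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(records))) {
        r <- records[i, ]
        writeLines(sprintf(">%s genome=%s contig=%s start=%d end=%d strand=%s",
                           r$id, r$genome_id, r$contig_id, r$start, r$end,
                           r$strand), con)
        seq <- r$sequence
        starts <- seq(1L, nchar(seq), by = width)
        writeLines(substring(seq, starts, pmin(starts + width - 1L, nchar(seq))),
                   con)
    }
    invisible(path)
}

#' Read or write a tab-delimited gene coordinate table
#'
#' Gene tables carry columns `genome_id`, `contig_id`, `gene_id`, `start`,
#' `end`, `strand` (1-based inclusive coordinates, GFF convention).
#'
#' @param path TSV file path.
#' @return `readGeneTable()` a `data.frame` with the columns above.
#' @export
readGeneTable <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("genome_id", "contig_id", "gene_id", "start", "end", "strand")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("gene table ", path, " lacks columns: ", paste(miss, collapse = ", "))
    if (any(tab$start > tab$end)) stop("gene table has start > end rows")
    if (anyDuplicated(tab[, c("genome_id", "gene_id")]))
        stop("duplicate (genome_id, gene_id) pairs in ", path)
    tab[need]
}

#' @rdname readGeneTable
#' @param table gene table `data.frame`.
#' @export
writeGeneTable <- function(table, path) {
    write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Load the packaged CYPome fixture tables
#'
#' Loads the packaged transcriptions of the published Salinispora CYPome
#' tables: per-strain P450/fragment/family/subfamily counts (`table2`),
#' per-family and per-subfamily counts (`table3`), and smBGC types with
#' their ordered P450 composition varieties (`table4`). A manifest of row
#' counts and column sums guards the transcription: any mismatch raises an
#' integrity error.
#'
#' @param dir directory holding `table2.tsv`, `table3.tsv`, `table4.tsv` and
#'   `manifest.json`; defaults to the copies installed with the package.
#' @return a list with elements `table2`, `table3`, `table4` (data.frames)
#'   and `manifest`.
#' @examples
#' fx <- loadFixtureTables()
#' nrow(fx$table2)                 # 126 strains
#' length(unique(fx$table3$family))  # 45 families
#' @export
loadFixtureTables <- function(dir = system.file("extdata", "fixtures",
                                                package = "cypome")) {
    paths <- file.path(dir, c("table2.tsv", "table3.tsv", "table4.tsv",
                              "manifest.json"))
    if (!all(file.exists(paths)))
        stop("fixture integrity error: missing files in ", dir)
    t2 <- read.delim(paths[1], stringsAsFactors = FALSE)
    t3 <- read.delim(paths[2], stringsAsFactors = FALSE)
    t4 <- read.delim(paths[3], stringsAsFactors = FALSE)
    man <- jsonlite::read_json(paths[4], simplifyVector = TRUE)

    famtab <- t3[!duplicated(t3$family), ]
    ok <- nrow(t2) == man$table2.tsv$n_rows &&
        sum(t2$n_p450) == man$table2.tsv$sum_n_p450 &&
        sum(t2$n_fragments) == man$table2.tsv$sum_n_fragments &&
        nrow(t3) == man$table3.tsv$n_rows &&
        length(unique(t3$family)) == man$table3.tsv$n_families &&
        sum(famtab$family_count) == man$table3.tsv$sum_family_counts &&
        sum(t3$subfamily_count) == man$table3.tsv$sum_subfamily_counts &&
        nrow(t4) == man$table4.tsv$n_rows &&
        length(unique(t4$bgc_type)) == man$table4.tsv$n_types &&
        sum(t4$p450_count) == man$table4.tsv$sum_p450_count
    if (!isTRUE(ok))
        stop("fixture integrity error: manifest checks failed for ", dir)
    if (!all(grepl("^CYP[0-9]+[A-Z0-9]*$", t3$family)))
        stop("fixture integrity error: malformed family name in table3")
    list(table2 = t2, table3 = t3, table4 = t4, manifest = man)
}

#' Write or read a phylogenetic tree in newick format
#'
#' Thin wrappers around [ape::write.tree()] / [ape::read.tree()] fixing the
#' branch-length precision and rejecting duplicate leaf labels.
#'
#' @param tree an [ape::phylo] tree with unique leaf labels.
#' @param path output file.
#' @param digits branch-length digits (default 6).
#' @return `writeNewickTree()` returns `path` invisibly; `readNewickTree()`
#'   an `ape::phylo`.
#' @export
writeNewickTree <- function(tree, path, digits = 6L) {
    if (anyDuplicated(tree$tip.label))
        stop("duplicate leaf labels: ",
             paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                   collapse = ", "))
    ape::write.tree(tree, file = path, digits = digits)
    invisible(path)
}

#' @rdname writeNewickTree
#' @export
readNewickTree <- function(path) ape::read.tree(path)
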