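.AA21 <- "ACDEFGHIKLMNPQRSTVWYX"

#' Motif-rule configuration
#'
#' Parameters of the P450/fragment decision rule. A complete P450 must carry
#' both diagnostic motifs -- the K-helix EXXR tetrapeptide and the
#' heme-binding CXG core -- in order, and reach a minimum length. The motifs
#' sit near the protein's C terminus, so by default candidate matches are
#' restricted to windows there, which suppresses chance matches of such
#' short patterns: EXXR must start in the C-terminal fraction
#' `exxrWindowFrac` of the sequence and CXG must lie within the final
#' `cxgWindowLen` residues.
#'
#' @param minLength minimum length (aa) of a complete P450; shorter
#'   sequences are at best fragments. Default 300, below the shortest
#'   complete bacterial P450s (~350-400 aa).
#' @param useWindows logical; disable to search the whole sequence.
#' @param exxrWindowFrac fraction of the sequence (from the C terminus)
#'   within which EXXR must start. Default 0.6.
#' @param cxgWindowLen length of the C-terminal window for CXG. Default 120.
#' @return a list of class `MotifConfig`.
#' @export
motifConfig <- function(minLength = 300L, useWindows = TRUE,
                        exxrWindowFrac = 0.6, cxgWindowLen = 120L) {
    stopifnot(minLength >= 1, exxrWindowFrac > 0, exxrWindowFrac <= 1,
              cxgWindowLen >= 3)
    structure(list(minLength = as.integer(minLength),
                   useWindows = isTRUE(useWindows),
                   exxrWindowFrac = exxrWindowFrac,
                   cxgWindowLen = as.integer(cxgWindowLen)),
              class = "MotifConfig")
}

.allMatches <- function(seq, pattern) {
    m <- gregexpr(pattern, seq, perl = TRUE)[[1]]
    if (m[1] == -1L) integer() else as.integer(m)
}

#' Locate the EXXR and CXG motifs in a protein sequence
#'
#' Scans for the K-helix `E-x-x-R` and heme-binding `C-x-G` patterns.
#' Wildcard positions accept any of the 21 letters (20 canonical residues
#' plus the ambiguity code X); the fixed letters E, R, C, G must match
#' exactly, so X never satisfies them. When windows are enabled (see
#' [motifConfig()]) only window-compliant matches are considered, and when
#' both motifs can be placed in order the CXG match is the last compliant
#' one with the latest EXXR strictly before it; otherwise each motif
#' reports its last match. Positions are 0-based.
#'
#' @param sequence uppercase amino-acid string over the 21-letter alphabet.
#' @param config a [motifConfig()].
#' @return a list with `has_exxr`, `exxr_position` (0-based index of E, or
#'   `NA`), `has_cxg`, `cxg_position` (0-based index of C, or `NA`),
#'   `ordered` (TRUE when EXXR lies entirely before CXG), `length_aa`.
#' @examples
#' findMotifs("MAAAETLRAAAAFGRRSHPCLGAAA", motifConfig(useWindows = FALSE))
#' @export
findMotifs <- function(sequence, config = motifConfig()) {
    if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
        stop("sequence must be a single non-empty string")
    if (grepl(sprintf("[^%s]", .AA21), sequence))
        stop("sequence contains letters outside the 21-letter amino-acid ",
             "alphabet: ",
             paste(unique(strsplit(gsub(sprintf("[%s]", .AA21), "",
                                        sequence), "")[[1]]), collapse = ""))
    L <- nchar(sequence)
    # lookahead finds overlapping matches
    exxr <- .allMatches(sequence, "(?=E..R)")
    cxg <- .allMatches(sequence, "(?=C.G)")
    if (config$useWindows) {
        exxr <- exxr[exxr > (1 - config$exxrWindowFrac) * L]
        cxg <- cxg[cxg >= L - config$cxgWindowLen + 1L & cxg + 2L <= L]
    } else {
        exxr <- exxr[exxr + 3L <= L]
    }
    ev <- list(has_exxr = length(exxr) > 0, exxr_position = NA_integer_,
               has_cxg = length(cxg) > 0, cxg_position = NA_integer_,
               ordered = FALSE, length_aa = L)
    # prefer an ordered placement: last CXG having an EXXR entirely before it
    pair_cxg <- cxg[vapply(cxg, function(p) any(exxr + 3L < p), logical(1))]
    if (length(pair_cxg)) {
        p <- max(pair_cxg)
        q <- max(exxr[exxr + 3L < p])
        ev$exxr_position <- q - 1L
        ev$cxg_position <- p - 1L
        ev$ordered <- TRUE
    } else {
        if (ev$has_exxr) ev$exxr_position <- max(exxr) - 1L
        if (ev$has_cxg) ev$cxg_position <- max(cxg) - 1L
    }
    ev
}

.classifyOne <- function(sequence, config) {
    ev <- findMotifs(sequence, config)
    both <- ev$has_exxr && ev$has_cxg
    status <- if (both && ev$ordered && ev$length_aa >= config$minLength)
        "P450"
    else if (ev$has_exxr || ev$has_cxg)
        "fragment"
    else
        "non-P450"
    c(list(status = status), ev)
}

#' Classify proteins as complete P450s, fragments, or non-P450s
#'
#' Applies the motif-and-length rule to each protein record: a sequence
#' carrying both diagnostic motifs in order (EXXR before CXG) at full
#' length (>= `minLength`) is a complete P450; a sequence with exactly one
#' motif, or with both motifs but short length, is a P450 fragment
#' (excluded from family/subfamily counts downstream); a sequence with
#' neither motif is not a P450. The rare case of both motifs present but
#' out of order is called a fragment so the three statuses partition the
#' input.
#'
#' @param records protein record `data.frame` from [readProteinFasta()].
#' @param config a [motifConfig()].
#' @return `records` with added columns `status`, `has_exxr`,
#'   `exxr_position`, `has_cxg`, `cxg_position`, `length_aa`.
#' @export
classifyProteins <- function(records, config = motifConfig()) {
    res <- lapply(records$sequence, .classifyOne, config = config)
    records$status <- vapply(res, `[[`, character(1), "status")
    records$has_exxr <- vapply(res, `[[`, logical(1), "has_exxr")
    records$exxr_position <- vapply(res, `[[`, integer(1), "exxr_position")
    records$has_cxg <- vapply(res, `[[`, logical(1), "has_cxg")
    records$cxg_position <- vapply(res, `[[`, integer(1), "cxg_position")
    records$length_aa <- vapply(res, `[[`, integer(1), "length_aa")
    records
}

#' Pre-filter records by precomputed P450 domain hits
#'
#' When a precomputed domain-hit table (e.g. InterPro IPR001128 presence)
#' is available, restricts the candidate set to flagged proteins before the
#' motif rule is applied. Without a table all records pass and the motif
#' rule alone governs.
#'
#' @param records protein record `data.frame`.
#' @param hits optional `data.frame` with columns `protein_id` and
#'   `has_ipr001128` (0/1 or logical). Ids absent from `records` raise a
#'   warning and are ignored.
#' @return the subset of `records` passing the filter.
#' @export
applyDomainPrefilter <- function(records, hits = NULL) {
    if (is.null(hits)) return(records)
    stopifnot(all(c("protein_id", "has_ipr001128") %in% names(hits)))
    unknown <- setdiff(hits$protein_id, records$id)
    if (length(unknown))
        warning("domain-hit table references unknown protein ids: ",
                paste(unknown, collapse = ", "))
    flagged <- hits$protein_id[as.logical(hits$has_ipr001128)]
    records[records$id %in% flagged, , drop = FALSE]
}
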