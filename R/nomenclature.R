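#' Alignment parameter set for percent-identity computation
#'
#' Percent identity between full-length P450 proteins is computed over a
#' global (Needleman-Wunsch) alignment. Defaults: BLOSUM62 substitution
#' scores, gap open 10, gap extend 0.5; identity is the fraction of
#' identical residue pairs among aligned residue pairs, gap columns
#' excluded.
#'
#' @param substitutionMatrix name of a substitution matrix shipped with
#'   Biostrings (default "BLOSUM62") or a numeric matrix.
#' @param gapOpening,gapExtension gap penalties (positive costs).
#' @return a list of class `AlignmentParams`.
#' @export
alignmentParams <- function(substitutionMatrix = "BLOSUM62",
                            gapOpening = 10, gapExtension = 0.5) {
    mat <- substitutionMatrix
    if (is.character(mat)) {
        env <- new.env()
        utils::data(list = mat, package = "Biostrings", envir = env)
        mat <- get(substitutionMatrix, envir = env)
    }
    structure(list(substitutionMatrix = mat, gapOpening = gapOpening,
                   gapExtension = gapExtension),
              class = "AlignmentParams")
}

.defaultParams <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) cache <<- alignmentParams()
        cache
    }
})

#' Global percent identity between two protein sequences
#'
#' Globally aligns two sequences and reports the percent identity over
#' aligned residue pairs (columns where both sequences have a residue; gap
#' columns are excluded from both numerator and denominator).
#'
#' @param seqA,seqB non-empty amino-acid strings.
#' @param params an [alignmentParams()].
#' @return a list with `identity_pct` (in [0, 100]), `n_aligned_pairs`,
#'   `aligned_a`, `aligned_b` (the gapped alignment rows, for independent
#'   rescoring), and `score`.
#' @examples
#' pairwiseIdentity("MAEELLRAGT", "MAEELLRAGT")$identity_pct  # 100
#' @export
pairwiseIdentity <- function(seqA, seqB, params = .defaultParams()) {
    if (!nzchar(seqA) || !nzchar(seqB))
        stop("sequences must be non-empty")
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqA), Biostrings::AAString(seqB),
        substitutionMatrix = params$substitutionMatrix,
        gapOpening = params$gapOpening,
        gapExtension = params$gapExtension,
        type = "global")
    a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    keep <- a != "-" & b != "-"
    n <- sum(keep)
    list(identity_pct = if (n > 0) 100 * sum(a[keep] == b[keep]) / n else 0,
         n_aligned_pairs = n,
         aligned_a = paste(a, collapse = ""),
         aligned_b = paste(b, collapse = ""),
         score = Biostrings::score(aln))
}

#' Nomenclature basis for a best-hit identity
#'
#' Applies the International P450 Nomenclature Committee thresholds with
#' strict inequalities: identity > 55 joins the best hit's subfamily,
#' 40 < identity <= 55 joins its family only, and identity <= 40 founds a
#' new family (identity exactly 40 or 55 falls to the lower tier).
#'
#' @param identityPct best-hit percent identity.
#' @param familyThreshold,subfamilyThreshold thresholds in percent
#'   (defaults 40 and 55).
#' @return one of `"subfamily-match"`, `"family-match"`, `"new-family"`.
#' @export
assignmentBasis <- function(identityPct, familyThreshold = 40,
                            subfamilyThreshold = 55) {
    ifelse(identityPct > subfamilyThreshold, "subfamily-match",
           ifelse(identityPct > familyThreshold, "family-match",
                  "new-family"))
}

#' Read a reference panel from FASTA
#'
#' Panel FASTA headers name each sequence by its full P450 name (e.g.
#' `>CYP105AB1`); any further header tokens are ignored and family/subfamily
#' are derived from the name.
#'
#' @param path FASTA file of named P450 protein sequences.
#' @return a [ReferencePanel-class].
#' @export
readReferencePanel <- function(path) {
    seqs <- Biostrings::readAAStringSet(path)
    names(seqs) <- sub("[[:space:]].*$", "", names(seqs))
    referencePanel(seqs)
}

#' Write a reference panel to FASTA
#'
#' @param panel a [ReferencePanel-class].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeReferencePanel <- function(panel, path) {
    seqs <- panelSequences(panel)
    names(seqs) <- sprintf("%s family=%s subfamily=%s", names(seqs),
                           panelFamily(panel), panelSubfamily(panel))
    Biostrings::writeXStringSet(seqs, path, width = 60L)
    invisible(path)
}

# single-linkage connected components over an identity matrix at > threshold;
# component ids numbered by first occurrence in input order
.components <- function(idm, threshold) {
    n <- nrow(idm)
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) i <- parent[i]
        i
    }
    if (n > 1) {
        for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
            if (idm[i, j] > threshold) {
                ri <- find(i); rj <- find(j)
                if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
            }
        }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    match(roots, unique(roots))  # component ids in first-occurrence order
}

#' Assign family and subfamily labels to P450 calls
#'
#' For each complete P450 the best panel hit (maximum global percent
#' identity; ties broken by lexicographically smallest reference name) is
#' found and the nomenclature thresholds applied (see [assignmentBasis()]).
#' Subfamily matches inherit the hit's family and subfamily; family matches
#' inherit the family and receive placeholder subfamilies `!1`, `!2`, ...
#' grouped by single-linkage at the subfamily threshold within the family;
#' queries below the family threshold to every panel entry are grouped among
#' themselves by single-linkage at the family threshold and founded as
#' placeholder families `CYPNEW-1`, `CYPNEW-2`, ... numbered by first
#' occurrence in input order.
#'
#' @param calls classified records from [classifyProteins()]; only rows with
#'   `status == "P450"` are assigned.
#' @param panel a non-empty [ReferencePanel-class].
#' @param params an [alignmentParams()].
#' @param familyThreshold,subfamilyThreshold percent-identity thresholds
#'   (defaults 40 and 55).
#' @return a `data.frame` with one row per complete P450: `query_id`,
#'   `genome_id`, `family`, `subfamily`, `basis`, `best_hit`,
#'   `best_identity_pct`.
#' @export
assignFamilies <- function(calls, panel, params = .defaultParams(),
                           familyThreshold = 40, subfamilyThreshold = 55) {
    if (length(panel) == 0) stop("reference panel is empty")
    p450 <- calls[calls$status == "P450", , drop = FALSE]
    out <- data.frame(query_id = character(), genome_id = character(),
                      family = character(), subfamily = character(),
                      basis = character(), best_hit = character(),
                      best_identity_pct = numeric(),
                      stringsAsFactors = FALSE)
    if (nrow(p450) == 0) return(out)
    pseq <- as.character(panelSequences(panel))
    pnames <- names(panel)
    ord <- order(pnames)  # scan in name order so ties keep the smallest name
    best_hit <- character(nrow(p450))
    best_pct <- numeric(nrow(p450))
    for (i in seq_len(nrow(p450))) {
        bh <- NA_character_; bp <- -1
        for (k in ord) {
            pid <- pairwiseIdentity(p450$sequence[i], pseq[k], params)
            if (pid$identity_pct > bp + 1e-9) {
                bp <- pid$identity_pct
                bh <- pnames[k]
            }
        }
        best_hit[i] <- bh
        best_pct[i] <- bp
    }
    basis <- assignmentBasis(best_pct, familyThreshold, subfamilyThreshold)
    fam <- panelFamily(panel)[best_hit]
    sub <- panelSubfamily(panel)[best_hit]
    family <- ifelse(basis == "new-family", NA_character_, unname(fam))
    subfamily <- ifelse(basis == "subfamily-match", unname(sub), NA_character_)

    # placeholder subfamilies: single-linkage at > subfamilyThreshold within family
    fm <- which(basis == "family-match")
    if (length(fm)) {
        for (f in unique(family[fm])) {
            idx <- fm[family[fm] == f]
            if (length(idx) == 1) {
                subfamily[idx] <- "!1"
            } else {
                idm <- diag(100, length(idx))
                for (a in seq_along(idx)) for (b in seq_along(idx)) {
                    if (b > a) {
                        idm[a, b] <- idm[b, a] <- pairwiseIdentity(
                            p450$sequence[idx[a]], p450$sequence[idx[b]],
                            params)$identity_pct
                    }
                }
                subfamily[idx] <- paste0("!", .components(idm, subfamilyThreshold))
            }
        }
    }

    # placeholder families: single-linkage at > familyThreshold among novel queries
    nf <- which(basis == "new-family")
    if (length(nf)) {
        if (length(nf) == 1) {
            family[nf] <- "CYPNEW-1"
        } else {
            idm <- diag(100, length(nf))
            for (a in seq_along(nf)) for (b in seq_along(nf)) {
                if (b > a) {
                    idm[a, b] <- idm[b, a] <- pairwiseIdentity(
                        p450$sequence[nf[a]], p450$sequence[nf[b]],
                        params)$identity_pct
                }
            }
            family[nf] <- paste0("CYPNEW-", .components(idm, familyThreshold))
        }
        subfamily[nf] <- "!1"
    }

    data.frame(query_id = p450$id, genome_id = p450$genome_id,
               family = family, subfamily = subfamily, basis = basis,
               best_hit = best_hit, best_identity_pct = best_pct,
               stringsAsFactors = FALSE)
}

#' Assign one P450 call against the panel
#'
#' Convenience single-query form of [assignFamilies()]; new families are
#' labelled `CYPNEW-1`.
#'
#' @inheritParams assignFamilies
#' @param call a single-row classified record with `status == "P450"`.
#' @return a one-row assignment `data.frame` (see [assignFamilies()]).
#' @export
assignFamily <- function(call, panel, params = .defaultParams(),
                         familyThreshold = 40, subfamilyThreshold = 55) {
    stopifnot(nrow(call) == 1, call$status == "P450")
    assignFamilies(call, panel, params, familyThreshold, subfamilyThreshold)
}

#' Write an assignment report TSV
#'
#' @param assignments result of [assignFamilies()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeAssignmentTable <- function(assignments, path) {
    write.table(assignments, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
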