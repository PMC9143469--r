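#' All-pairs identity distance matrix
#'
#' Computes global percent identity (see [pairwiseIdentity()]) for every
#' sequence pair and converts it to a distance `d = 1 - identity/100`.
#' Quadratic in the number of sequences; for large CYPomes use a
#' representative subset (see [runPipeline()]'s `treeMaxPerFamily`).
#'
#' @param sequences named character vector (or protein record `data.frame`
#'   with `id` and `sequence` columns) of >= 3 protein sequences.
#' @param params an [alignmentParams()].
#' @return a symmetric numeric matrix with zero diagonal, labelled by
#'   sequence id.
#' @export
buildDistanceMatrix <- function(sequences, params = .defaultParams()) {
    if (is.data.frame(sequences))
        sequences <- setNames(sequences$sequence, sequences$id)
    n <- length(sequences)
    if (n < 3) stop("need at least 3 sequences")
    if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
        stop("sequences must have unique names")
    d <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        pid <- pairwiseIdentity(sequences[[i]], sequences[[j]], params)
        d[i, j] <- d[j, i] <- 1 - pid$identity_pct / 100
    }
    d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (exact on additive distance matrices),
#' returning an unrooted tree. Negative branch lengths -- a known NJ
#' artifact on non-additive input -- are clamped to zero and the number of
#' clamped edges recorded in the `"clampedEdges"` attribute.
#'
#' @param dist symmetric distance matrix with labels (from
#'   [buildDistanceMatrix()]), n >= 3.
#' @param tol symmetry tolerance.
#' @return an unrooted [ape::phylo] tree.
#' @export
njTree <- function(dist, tol = 1e-9) {
    if (!is.matrix(dist) || nrow(dist) != ncol(dist))
        stop("dist must be a square matrix")
    if (max(abs(dist - t(dist))) > tol)
        stop("distance matrix is not symmetric")
    if (is.null(rownames(dist))) stop("distance matrix must be labelled")
    tree <- ape::nj(as.dist(dist))
    clamped <- sum(tree$edge.length < 0)
    tree$edge.length[tree$edge.length < 0] <- 0
    attr(tree, "clampedEdges") <- clamped
    tree
}

#' Family color annotation for tree leaves
#'
#' Maps every leaf to its assigned family and gives the `k` most abundant
#' families (by leaf count; ties broken by family name) distinct color
#' indices 1..k, leaving the rest uncolored (`NA`).
#'
#' @param tree an [ape::phylo] tree whose tip labels are P450 ids.
#' @param assignments assignment table from [assignFamilies()] covering
#'   every leaf.
#' @param k number of top families to color (default 8).
#' @return a `data.frame` with `leaf_id`, `family`, `color_index`.
#' @export
familyColoring <- function(tree, assignments, k = 8L) {
    fam <- assignments$family[match(tree$tip.label, assignments$query_id)]
    if (anyNA(fam))
        stop("missing family assignment for leaves: ",
             paste(tree$tip.label[is.na(fam)], collapse = ", "))
    cnt <- table(fam)
    ord <- order(-as.integer(cnt), names(cnt))
    top <- names(cnt)[ord][seq_len(min(k, length(cnt)))]
    data.frame(leaf_id = tree$tip.label, family = fam,
               color_index = match(fam, top), stringsAsFactors = FALSE)
}

#' Monophyly of planted families in an unrooted tree
#'
#' Utility for property checks on simulated data: tests whether each
#' family's leaves form a clade in the induced unrooted sense (some edge of
#' the tree splits exactly that leaf set from the rest).
#'
#' @param tree an [ape::phylo] tree.
#' @param families named character vector mapping tip label to family.
#' @return named logical vector, one entry per family.
#' @export
familyMonophyly <- function(tree, families) {
    families <- families[tree$tip.label]
    ntip <- length(tree$tip.label)
    # leaf sets under each internal edge
    splits <- lapply(seq_len(nrow(tree$edge)), function(e) {
        node <- tree$edge[e, 2]
        if (node <= ntip) tree$tip.label[node]
        else ape::extract.clade(tree, node)$tip.label
    })
    vapply(unique(families), function(f) {
        leaves <- sort(names(families)[families == f])
        if (length(leaves) <= 1 || length(leaves) >= ntip - 1) return(TRUE)
        any(vapply(splits, function(s)
            identical(sort(s), leaves) ||
            identical(sort(setdiff(tree$tip.label, s)), leaves),
            logical(1)))
    }, logical(1))
}
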