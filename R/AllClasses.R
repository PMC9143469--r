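#' @import methods
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom stats dist hclust as.dist cophenetic runif setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

.FAMILY_RE <- "^CYP[0-9]+"

#' Reference panel of named P450 sequences
#'
#' Holds the named cytochrome P450 protein sequences against which query
#' P450s are classified. Each entry carries a full nomenclature name
#' (e.g. \code{CYP105AB1}), from which the family (\code{CYP} + digits) and
#' subfamily (the letter block following the family digits) are derived.
#'
#' @slot sequences an [Biostrings::AAStringSet] of panel sequences, named by
#'   the full P450 name.
#' @slot family character vector of family labels, parallel to `sequences`.
#' @slot subfamily character vector of subfamily labels, parallel to
#'   `sequences`.
#'
#' @seealso [referencePanel()], [readReferencePanel()], [assignFamilies()]
#' @exportClass ReferencePanel
setClass("ReferencePanel",
    representation(
        sequences = "AAStringSet",
        family = "character",
        subfamily = "character"
    )
)

setValidity("ReferencePanel", function(object) {
    n <- length(object@sequences)
    nm <- names(object@sequences)
    msg <- character()
    if (n > 0 && (is.null(nm) || anyNA(nm) || any(nm == "")))
        msg <- c(msg, "all panel sequences must be named")
    else if (anyDuplicated(nm))
        msg <- c(msg, "panel names must be unique")
    if (length(object@family) != n || length(object@subfamily) != n)
        msg <- c(msg, "family and subfamily must parallel sequences")
    if (n > 0 && !is.null(nm)) {
        expect_fam <- regmatches(nm, regexpr(.FAMILY_RE, nm))
        if (length(expect_fam) == n && !all(object@family == expect_fam))
            msg <- c(msg, "family must equal the leading CYP+digits of the name")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ReferencePanel
#'
#' @param sequences named character vector or [Biostrings::AAStringSet] of
#'   panel protein sequences; names are full P450 names such as
#'   \code{CYP105AB1}.
#' @return a [ReferencePanel-class] object. Family and subfamily labels are
#'   parsed from the names: family is the leading \code{CYP}+digits, the
#'   subfamily is the letter block that follows (empty when the name stops at
#'   the family).
#' @examples
#' referencePanel(c(CYP105AB1 = "MAEELLRAG", CYP107W1 = "MTECAGLLK"))
#' @export
referencePanel <- function(sequences) {
    if (is.character(sequences))
        sequences <- Biostrings::AAStringSet(sequences)
    nm <- names(sequences)
    if (length(sequences) == 0)
        return(new("ReferencePanel", sequences = sequences,
                   family = character(), subfamily = character()))
    if (is.null(nm)) stop("panel sequences must be named")
    fam <- regmatches(nm, regexpr(.FAMILY_RE, nm))
    if (length(fam) != length(nm))
        stop("every panel name must match ", .FAMILY_RE)
    rest <- substring(nm, nchar(fam) + 1L)
    sub <- sub("[0-9].*$", "", rest)
    new("ReferencePanel", sequences = sequences, family = fam, subfamily = sub)
}

#' @describeIn ReferencePanel-class number of panel entries
#' @param x a `ReferencePanel`
#' @export
setMethod("length", "ReferencePanel", function(x) length(x@sequences))

#' @describeIn ReferencePanel-class panel entry names
#' @export
setMethod("names", "ReferencePanel", function(x) names(x@sequences))

#' Accessors for ReferencePanel
#'
#' @param x a [ReferencePanel-class]
#' @return `panelSequences()` the AAStringSet; `panelFamily()` /
#'   `panelSubfamily()` character vectors named by entry.
#' @export
panelSequences <- function(x) x@sequences

#' @rdname panelSequences
#' @export
panelFamily <- function(x) setNames(x@family, names(x@sequences))

#' @rdname panelSequences
#' @export
panelSubfamily <- function(x) setNames(x@subfamily, names(x@sequences))

setMethod("show", "ReferencePanel", function(object) {
    cat("ReferencePanel with", length(object), "named P450s in",
        length(unique(object@family)), "families\n")
    n <- min(5L, length(object))
    if (n > 0)
        cat("  ", paste(utils::head(names(object), n), collapse = ", "),
            if (length(object) > n) ", ..." else "", "\n", sep = "")
})

#' CYPome profile: genome-by-family P450 count matrix
#'
#' The central container of the profiling stage: a matrix of P450 counts
#' with genomes as rows and P450 families as columns, plus the per-genome
#' count of P450 fragments (sequences excluded from family totals).
#'
#' @slot counts integer matrix, genomes x families.
#' @slot fragments integer vector of per-genome fragment counts, named by
#'   genome.
#'
#' @seealso [buildProfile()], [computeStats()], [clusterHeatmap()]
#' @exportClass CypomeProfile
setClass("CypomeProfile",
    representation(counts = "matrix", fragments = "integer")
)

setValidity("CypomeProfile", function(object) {
    m <- object@counts
    msg <- character()
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msg <- c(msg, "counts must have genome rownames and family colnames")
    if (any(m < 0) || any(m != round(m)))
        msg <- c(msg, "counts must be non-negative integers")
    if (length(object@fragments) != nrow(m))
        msg <- c(msg, "fragments must have one entry per genome")
    else if (!identical(names(object@fragments), rownames(m)))
        msg <- c(msg, "fragments names must match genome rownames")
    if (length(msg)) msg else TRUE
})

#' @describeIn CypomeProfile-class genome and family dimensions
#' @param x a `CypomeProfile`
#' @export
setMethod("dim", "CypomeProfile", function(x) dim(x@counts))

#' Accessors for CypomeProfile
#'
#' @param x a [CypomeProfile-class]
#' @return `profileCounts()` the genome x family count matrix;
#'   `genomeNames()` / `familyNames()` the dimension names;
#'   `fragmentCounts()` the named per-genome fragment vector.
#' @export
profileCounts <- function(x) x@counts

#' @rdname profileCounts
#' @export
genomeNames <- function(x) rownames(x@counts)

#' @rdname profileCounts
#' @export
familyNames <- function(x) colnames(x@counts)

#' @rdname profileCounts
#' @export
fragmentCounts <- function(x) x@fragments

setMethod("show", "CypomeProfile", function(object) {
    cat("CypomeProfile:", nrow(object@counts), "genomes x",
        ncol(object@counts), "P450 families;",
        sum(object@counts), "P450s,", sum(object@fragments), "fragments\n")
})

#' Clustered presence/absence heat-map matrix
#'
#' Result of [clusterHeatmap()]: the -3/3 presence encoding of a
#' [CypomeProfile-class] together with the row/column orders and dendrograms
#' from Euclidean hierarchical clustering.
#'
#' @slot values matrix over \{-3, 3\}: 3 where the family is present in the
#'   genome, -3 where absent.
#' @slot rowOrder,colOrder integer permutations placing clustered rows and
#'   columns in dendrogram order.
#' @slot rowDendro,colDendro `hclust` objects (or `NULL` for degenerate
#'   input).
#' @exportClass CypomeHeatmap
setClass("CypomeHeatmap",
    representation(
        values = "matrix",
        rowOrder = "integer",
        colOrder = "integer",
        rowDendro = "ANY",
        colDendro = "ANY"
    )
)

setValidity("CypomeHeatmap", function(object) {
    msg <- character()
    if (!all(object@values %in% c(-3, 3)))
        msg <- c(msg, "values must contain only -3 and 3")
    if (!identical(sort(object@rowOrder), seq_len(nrow(object@values))))
        msg <- c(msg, "rowOrder must be a permutation of rows")
    if (!identical(sort(object@colOrder), seq_len(ncol(object@values))))
        msg <- c(msg, "colOrder must be a permutation of columns")
    if (length(msg)) msg else TRUE
})

#' Accessors for CypomeHeatmap
#'
#' @param x a [CypomeHeatmap-class]
#' @return `heatmapValues()` the -3/3 matrix; `heatmapRowOrder()` /
#'   `heatmapColOrder()` the clustering permutations.
#' @export
heatmapValues <- function(x) x@values

#' @rdname heatmapValues
#' @export
heatmapRowOrder <- function(x) x@rowOrder

#' @rdname heatmapValues
#' @export
heatmapColOrder <- function(x) x@colOrder

setMethod("show", "CypomeHeatmap", function(object) {
    cat("CypomeHeatmap:", nrow(object@values), "x", ncol(object@values),
        "presence/absence matrix (-3 absent / 3 present), clustered\n")
})
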