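#' @import methods
NULL

#' GeneSet: a named collection of normalized gene symbols
#'
#' A `GeneSet` stores a set label and a duplicate-free vector of gene
#' symbols. Symbols are normalized on construction (trimmed, uppercased)
#' so that set operations are case-insensitive and order-independent.
#'
#' @slot setName Character scalar, the label of the set.
#' @slot geneIds Character vector of unique, normalized gene symbols.
#'
#' @seealso [GeneSet()], [readGeneList()], [normalizeSymbols()]
#' @name GeneSet-class
#' @rdname GeneSet-class
#' @exportClass GeneSet
setClass("GeneSet",
    representation(setName = "character", geneIds = "character"))

setValidity("GeneSet", function(object) {
    msg <- character()
    if (length(object@setName) != 1L || is.na(object@setName) ||
        !nzchar(object@setName))
        msg <- c(msg, "'setName' must be a single non-empty string")
    if (anyDuplicated(object@geneIds))
        msg <- c(msg, "'geneIds' must not contain duplicates")
    if (length(object@geneIds) &&
        !identical(object@geneIds, normalizeSymbols(object@geneIds)))
        msg <- c(msg, "'geneIds' must be normalized (trimmed, uppercase)")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSet
#'
#' Symbols are normalized with [normalizeSymbols()] and duplicates (after
#' normalization) are collapsed, keeping first occurrence order.
#'
#' @param setName Character scalar label.
#' @param geneIds Character vector of gene symbols (raw; normalized here).
#' @return A [GeneSet-class] object.
#' @examples
#' gs <- GeneSet("down.in.aging", c("smpx", "Myl3", "SMPX"))
#' length(gs)  # 2
#' @export
GeneSet <- function(setName, geneIds = character()) {
    ids <- if (length(geneIds)) normalizeSymbols(geneIds) else character()
    new("GeneSet", setName = as.character(setName),
        geneIds = unique(ids))
}

#' GeneSetLibrary: a collection of term -> gene-set mappings
#'
#' Libraries map term identifiers (pathways, annotation categories,
#' regulators) to member gene sets, together with the size `N` of the
#' gene universe used by over-representation tests.
#'
#' @slot libraryName Character scalar label.
#' @slot sets Named list; each element a character vector of normalized
#'   gene symbols (non-empty).
#' @slot universeSize Integer scalar, the universe size `N`; must be at
#'   least the size of the union of all member sets.
#'
#' @seealso [GeneSetLibrary()], [readGMT()], [enrichLibrary()]
#' @name GeneSetLibrary-class
#' @rdname GeneSetLibrary-class
#' @exportClass GeneSetLibrary
setClass("GeneSetLibrary",
    representation(libraryName = "character", sets = "list",
                   universeSize = "integer"))

setValidity("GeneSetLibrary", function(object) {
    msg <- character()
    if (length(object@libraryName) != 1L || !nzchar(object@libraryName))
        msg <- c(msg, "'libraryName' must be a single non-empty string")
    nm <- names(object@sets)
    if (length(object@sets)) {
        if (is.null(nm) || any(!nzchar(nm)))
            msg <- c(msg, "every term must be named")
        if (anyDuplicated(nm))
            msg <- c(msg, sprintf("duplicate term identifier(s): %s",
                paste(unique(nm[duplicated(nm)]), collapse = ", ")))
        sizes <- lengths(object@sets)
        if (any(sizes == 0L))
            msg <- c(msg, "every member set must be non-empty")
    }
    if (length(object@universeSize) != 1L || is.na(object@universeSize) ||
        object@universeSize < 1L)
        msg <- c(msg, "'universeSize' must be a positive integer")
    else {
        u <- length(unique(unlist(object@sets, use.names = FALSE)))
        if (object@universeSize < u)
            msg <- c(msg, sprintf(
                "universeSize (%d) smaller than union of member sets (%d)",
                object@universeSize, u))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSetLibrary
#'
#' @param libraryName Character scalar label.
#' @param sets Named list of character vectors (term -> member symbols);
#'   members are normalized and de-duplicated.
#' @param universeSize Universe size `N` for enrichment; defaults to
#'   20000 (or the union size, if larger).
#' @return A [GeneSetLibrary-class] object.
#' @examples
#' lib <- GeneSetLibrary("toy",
#'     list(T1 = c("A", "B", "C"), T2 = c("b", "d")),
#'     universeSize = 100)
#' length(lib)  # 2
#' @export
GeneSetLibrary <- function(libraryName, sets, universeSize = 20000L) {
    sets <- lapply(sets, function(g) unique(normalizeSymbols(g)))
    u <- length(unique(unlist(sets, use.names = FALSE)))
    new("GeneSetLibrary", libraryName = as.character(libraryName),
        sets = sets, universeSize = as.integer(max(universeSize, u)))
}

#' RegulatorLibrary: regulator -> target gene sets from one evidence source
#'
#' A [GeneSetLibrary-class] whose terms are upstream regulators (kinases,
#' transcription factors) and whose member sets are their known targets.
#' The class exists so that regulator-specific methods (per-source exact
#' tests, mean-rank aggregation) dispatch on the right container.
#'
#' @name RegulatorLibrary-class
#' @rdname RegulatorLibrary-class
#' @exportClass RegulatorLibrary
setClass("RegulatorLibrary", contains = "GeneSetLibrary")

#' Construct a RegulatorLibrary
#'
#' @inheritParams GeneSetLibrary
#' @param sets Named list regulator -> character vector of target symbols.
#' @return A [RegulatorLibrary-class] object.
#' @export
RegulatorLibrary <- function(libraryName, sets, universeSize = 20000L) {
    as(GeneSetLibrary(libraryName, sets, universeSize), "RegulatorLibrary")
}

#' AnnotationCategory: one evidence channel for functional similarity
#'
#' A category is either *categorical* (gene -> set of term identifiers,
#' e.g. GO terms) or *quantitative* (gene -> fixed-length numeric vector,
#' e.g. an expression profile). Exactly one payload is populated.
#'
#' @slot categoryName Character scalar label.
#' @slot kind Either `"categorical"` or `"quantitative"`.
#' @slot terms Named list gene -> character vector of term ids
#'   (categorical payload; empty list otherwise).
#' @slot profiles Numeric matrix with gene rownames (quantitative
#'   payload; 0 x 0 matrix otherwise).
#'
#' @seealso [AnnotationCategory()], [buildTrainingProfile()]
#' @name AnnotationCategory-class
#' @rdname AnnotationCategory-class
#' @exportClass AnnotationCategory
setClass("AnnotationCategory",
    representation(categoryName = "character", kind = "character",
                   terms = "list", profiles = "matrix"))

setValidity("AnnotationCategory", function(object) {
    msg <- character()
    if (!object@kind %in% c("categorical", "quantitative"))
        msg <- c(msg, "'kind' must be 'categorical' or 'quantitative'")
    if (object@kind == "categorical") {
        if (nrow(object@profiles) || ncol(object@profiles))
            msg <- c(msg, "categorical category must have empty 'profiles'")
        if (length(object@terms) &&
            (is.null(names(object@terms)) || any(!nzchar(names(object@terms)))))
            msg <- c(msg, "'terms' must be a named (by gene) list")
    } else if (object@kind == "quantitative") {
        if (length(object@terms))
            msg <- c(msg, "quantitative category must have empty 'terms'")
        if (nrow(object@profiles) && is.null(rownames(object@profiles)))
            msg <- c(msg, "'profiles' must have gene rownames")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an AnnotationCategory
#'
#' @param categoryName Character scalar label.
#' @param kind `"categorical"` or `"quantitative"`.
#' @param terms Named list gene -> character vector of term identifiers
#'   (categorical only).
#' @param profiles Numeric matrix, genes in rows (quantitative only).
#' @return An [AnnotationCategory-class] object.
#' @export
AnnotationCategory <- function(categoryName,
                               kind = c("categorical", "quantitative"),
                               terms = list(), profiles = NULL) {
    kind <- match.arg(kind)
    if (kind == "categorical") {
        if (length(terms))
            names(terms) <- normalizeSymbols(names(terms))
        profiles <- matrix(numeric(), 0L, 0L)
    } else {
        if (is.null(profiles))
            stop("quantitative category requires a 'profiles' matrix")
        rownames(profiles) <- normalizeSymbols(rownames(profiles))
        terms <- list()
    }
    new("AnnotationCategory", categoryName = as.character(categoryName),
        kind = kind, terms = terms, profiles = profiles)
}

#' PPINetwork: an undirected protein-protein interaction graph
#'
#' Stores an undirected simple graph as a node vector plus an edge table
#' with optional confidence weights in (0, 1]. Self-loops and duplicate
#' edges are rejected by the validity method.
#'
#' @slot nodes Character vector of normalized gene symbols.
#' @slot edges A data.frame with columns `from`, `to` and `weight`.
#'
#' @seealso [PPINetwork()], [readEdgeList()], [pagerankWithPriors()]
#' @name PPINetwork-class
#' @rdname PPINetwork-class
#' @exportClass PPINetwork
setClass("PPINetwork",
    representation(nodes = "character", edges = "data.frame"))

setValidity("PPINetwork", function(object) {
    msg <- character()
    e <- object@edges
    if (!all(c("from", "to", "weight") %in% names(e)))
        msg <- c(msg, "'edges' must have columns from, to, weight")
    else {
        if (any(e$from == e$to))
            msg <- c(msg, "self-loops are not allowed")
        if (!all(e$from %in% object@nodes) || !all(e$to %in% object@nodes))
            msg <- c(msg, "every edge endpoint must be a node")
        key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate edges are not allowed")
        if (any(!is.finite(e$weight)) || any(e$weight <= 0) ||
            any(e$weight > 1))
            msg <- c(msg, "edge weights must lie in (0, 1]")
    }
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "duplicate nodes are not allowed")
    if (length(msg)) msg else TRUE
})

#' Construct a PPINetwork
#'
#' @param edges A data.frame (or two/three-column matrix-like) with
#'   columns interactor A, interactor B and an optional confidence weight
#'   in (0, 1] (defaults to 1).
#' @param nodes Optional character vector of nodes; defaults to the edge
#'   endpoints. Extra entries become isolated nodes.
#' @return A [PPINetwork-class] object.
#' @examples
#' net <- PPINetwork(data.frame(from = c("A", "B"), to = c("B", "C")))
#' length(net)  # 3 nodes
#' @export
PPINetwork <- function(edges, nodes = NULL) {
    edges <- as.data.frame(edges)
    if (ncol(edges) < 2L)
        stop("'edges' needs at least two columns")
    from <- normalizeSymbols(as.character(edges[[1L]]))
    to <- normalizeSymbols(as.character(edges[[2L]]))
    weight <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]])
              else rep(1, length(from))
    nodes <- if (is.null(nodes)) unique(c(from, to))
             else unique(c(normalizeSymbols(nodes), from, to))
    new("PPINetwork", nodes = nodes,
        edges = data.frame(from = from, to = to, weight = weight,
                           stringsAsFactors = FALSE))
}

## ---- show methods ------------------------------------------------------

setMethod("show", "GeneSet", function(object) {
    cat("GeneSet \"", object@setName, "\" with ", length(object@geneIds),
        " gene(s)\n", sep = "")
    if (length(object@geneIds)) {
        preview <- utils::head(object@geneIds, 6L)
        cat("  ", paste(preview, collapse = ", "),
            if (length(object@geneIds) > 6L) ", ..." else "", "\n", sep = "")
    }
})

setMethod("show", "GeneSetLibrary", function(object) {
    cat(class(object), " \"", object@libraryName, "\": ",
        length(object@sets), " term(s), universe N = ",
        object@universeSize, "\n", sep = "")
    if (length(object@sets)) {
        preview <- utils::head(names(object@sets), 4L)
        cat("  terms: ", paste(preview, collapse = ", "),
            if (length(object@sets) > 4L) ", ..." else "", "\n", sep = "")
    }
})

setMethod("show", "AnnotationCategory", function(object) {
    n <- if (object@kind == "categorical") length(object@terms)
         else nrow(object@profiles)
    cat("AnnotationCategory \"", object@categoryName, "\" (", object@kind,
        "): ", n, " annotated gene(s)\n", sep = "")
})

setMethod("show", "PPINetwork", function(object) {
    cat("PPINetwork: ", length(object@nodes), " node(s), ",
        nrow(object@edges), " edge(s)\n", sep = "")
})
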