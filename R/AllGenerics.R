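#' Accessors for priorank classes
#'
#' Small accessor generics: `geneIds()` returns the member symbols of a
#' [GeneSet-class]; `setName()` its label; `libraryName()`,
#' `universeSize()` and `geneSets()` the fields of a
#' [GeneSetLibrary-class]; `categoryName()` and `categoryKind()` the
#' fields of an [AnnotationCategory-class]; `nodes()` and `edges()` those
#' of a [PPINetwork-class].
#'
#' @param x An object of the documented class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))
#' @rdname accessors
#' @export
setGeneric("libraryName", function(x) standardGeneric("libraryName"))
#' @rdname accessors
#' @export
setGeneric("universeSize", function(x) standardGeneric("universeSize"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("categoryName", function(x) standardGeneric("categoryName"))
#' @rdname accessors
#' @export
setGeneric("categoryKind", function(x) standardGeneric("categoryKind"))
#' @rdname accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))
#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname accessors
#' @export
setMethod("geneIds", "GeneSet", function(x) x@geneIds)
#' @rdname accessors
#' @export
setMethod("setName", "GeneSet", function(x) x@setName)
#' @rdname accessors
#' @export
setMethod("libraryName", "GeneSetLibrary", function(x) x@libraryName)
#' @rdname accessors
#' @export
setMethod("universeSize", "GeneSetLibrary", function(x) x@universeSize)
#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetLibrary", function(x) x@sets)
#' @rdname accessors
#' @export
setMethod("categoryName", "AnnotationCategory", function(x) x@categoryName)
#' @rdname accessors
#' @export
setMethod("categoryKind", "AnnotationCategory", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("nodes", "PPINetwork", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("edges", "PPINetwork", function(x) x@edges)

#' @describeIn GeneSet-class Number of member genes.
#' @param x A `GeneSet`.
#' @export
setMethod("length", "GeneSet", function(x) length(x@geneIds))

#' @describeIn GeneSetLibrary-class Number of terms.
#' @param x A `GeneSetLibrary`.
#' @export
setMethod("length", "GeneSetLibrary", function(x) length(x@sets))

#' @describeIn GeneSetLibrary-class Term identifiers.
#' @export
setMethod("names", "GeneSetLibrary", function(x) names(x@sets))

#' @describeIn GeneSetLibrary-class Member symbols of one term.
#' @param i Term identifier or index.
#' @export
setMethod("[[", "GeneSetLibrary", function(x, i) x@sets[[i]])

#' @describeIn PPINetwork-class Number of nodes.
#' @param x A `PPINetwork`.
#' @export
setMethod("length", "PPINetwork", function(x) length(x@nodes))
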