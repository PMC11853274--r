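#' Accessor generics
#'
#' Small accessor generics used across the package's S4 classes.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @return The corresponding slot content (see the methods' documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))

#' @rdname accessors
#' @export
setGeneric("kmerNames", function(x) standardGeneric("kmerNames"))

#' @rdname accessors
#' @export
setGeneric("subsetMembers", function(x, pattern, ...)
  standardGeneric("subsetMembers"))

#' @rdname accessors
#' @export
setGeneric("subsetSizes", function(x) standardGeneric("subsetSizes"))

#' @rdname accessors
#' @export
setGeneric("donorSites", function(x) standardGeneric("donorSites"))

#' @rdname accessors
#' @export
setGeneric("acceptorSites", function(x) standardGeneric("acceptorSites"))

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname accessors
#' @export
setGeneric("windowSequences", function(x) standardGeneric("windowSequences"))

#' @rdname accessors
#' @export
setGeneric("windowInfo", function(x) standardGeneric("windowInfo"))

#' @rdname accessors
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' @rdname accessors
#' @export
setGeneric("kmerCounts", function(x) standardGeneric("kmerCounts"))

#' @rdname accessors
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @rdname accessors
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))

#' @rdname accessors
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))
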