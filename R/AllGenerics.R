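#' Accessors for svprob classes
#'
#' `fragmentAlignments()` returns the fragment-alignment table;
#' `libraryStats()` the [LibraryStats-class]; `fragmentClass()` the
#' per-fragment partition; `breakendVertices()` the polygon vertex matrix;
#' `isEmpty()` tests polygon emptiness; `candidates()` the candidate list;
#' `marginalSupport()` the chain marginals; `svCallTable()` the call
#' data.frame; `lambdaC()` / `lambdaD()` the derived Poisson means.
#'
#' @param x,object An svprob object.
#' @return The accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fragmentAlignments",
           function(x) standardGeneric("fragmentAlignments"))
#' @rdname accessors
#' @export
setGeneric("libraryStats", function(x) standardGeneric("libraryStats"))
#' @rdname accessors
#' @export
setGeneric("fragmentClass", function(x) standardGeneric("fragmentClass"))
#' @rdname accessors
#' @export
setGeneric("breakendVertices",
           function(x) standardGeneric("breakendVertices"))
#' @rdname accessors
#' @export
setGeneric("isEmpty", function(x) standardGeneric("isEmpty"))
#' @rdname accessors
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))
#' @rdname accessors
#' @export
setGeneric("marginalSupport", function(x) standardGeneric("marginalSupport"))
#' @rdname accessors
#' @export
setGeneric("svCallTable", function(x) standardGeneric("svCallTable"))
#' @rdname accessors
#' @export
setGeneric("lambdaC", function(x) standardGeneric("lambdaC"))
#' @rdname accessors
#' @export
setGeneric("lambdaD", function(x) standardGeneric("lambdaD"))

#' @rdname accessors
setMethod("fragmentAlignments", "SVFragments", function(x) x@alignments)
#' @rdname accessors
setMethod("libraryStats", "SVFragments", function(x) x@stats)
#' @rdname accessors
setMethod("fragmentClass", "SVFragments", function(x) x@fragClass)
#' @rdname accessors
setMethod("breakendVertices", "BreakendPolygon", function(x) x@vertices)
#' @rdname accessors
setMethod("isEmpty", "BreakendPolygon", function(x) nrow(x@vertices) == 0L)
#' @rdname accessors
setMethod("candidates", "SVCandidateSet", function(x) x@candidates)
#' @rdname accessors
setMethod("marginalSupport", "ChainSummary", function(x) x@mbar)
#' @rdname accessors
setMethod("svCallTable", "SVCalls", function(x) x@calls)
#' @rdname accessors
setMethod("lambdaC", "ModelParams", function(x) x@lambda * x@lavg)
#' @rdname accessors
setMethod("lambdaD", "ModelParams",
          function(x) (x@lavg - 2 * x@readLength) * x@lambda)
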