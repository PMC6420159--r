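#' @rdname testabilityMask
#' @export
setGeneric("testabilityMask", function(x, ...) standardGeneric("testabilityMask"))

#' @rdname prevalenceVector
#' @export
setGeneric("prevalenceVector", function(x, ...) standardGeneric("prevalenceVector"))

#' @rdname inferNetwork
#' @export
setGeneric("inferNetwork", function(x, ...) standardGeneric("inferNetwork"))

#' Accessors for TestabilityMask objects
#'
#' \code{maskCategories} returns the OTU-by-OTU matrix of four-way
#' categories (\code{"full"}, \code{"positive_only"},
#' \code{"negative_only"}, \code{"none"}; diagonal \code{NA}), or with
#' \code{encoded = TRUE} the integer coding 2/1/-1/0 of the same;
#' \code{positiveTestable} and \code{negativeTestable} return the logical
#' verdict matrices; \code{problematicPairs} returns the logical matrix of
#' pairs that are not fully testable (the pairs excluded by
#' testability-based filtering).
#'
#' @param x a \code{\linkS4class{TestabilityMask}}.
#' @param ... for \code{maskCategories}: \code{encoded = TRUE} selects the
#'   integer coding.
#' @return a matrix as described above.
#' @name mask-accessors
#' @rdname mask-accessors
#' @export
setGeneric("maskCategories", function(x, ...) standardGeneric("maskCategories"))

#' @rdname mask-accessors
#' @export
setGeneric("positiveTestable", function(x) standardGeneric("positiveTestable"))

#' @rdname mask-accessors
#' @export
setGeneric("negativeTestable", function(x) standardGeneric("negativeTestable"))

#' @rdname mask-accessors
#' @export
setGeneric("problematicPairs", function(x) standardGeneric("problematicPairs"))

#' Accessors for SimulatedCommunity objects
#'
#' \code{truthAdjacency} returns the ground-truth signed adjacency matrix
#' (-1/0/+1); \code{latentCorrelation} the generating latent correlation
#' matrix; \code{targetPrevalence} the per-OTU structural prevalences the
#' marginals were parameterized with (realized prevalence, computable with
#' \code{\link{prevalenceVector}}, is slightly lower because the negative
#' binomial component itself can produce zeros).
#'
#' @param x a \code{\linkS4class{SimulatedCommunity}}.
#' @return a matrix (adjacency, correlation) or numeric vector.
#' @name community-accessors
#' @rdname community-accessors
#' @export
setGeneric("truthAdjacency", function(x) standardGeneric("truthAdjacency"))

#' @rdname community-accessors
#' @export
setGeneric("latentCorrelation", function(x) standardGeneric("latentCorrelation"))

#' @rdname community-accessors
#' @export
setGeneric("targetPrevalence", function(x) standardGeneric("targetPrevalence"))

#' @rdname edgeTable
#' @export
setGeneric("edgeTable", function(x, ...) standardGeneric("edgeTable"))
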