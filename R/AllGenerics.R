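#' @rdname mapperAccessors
#' @export
setGeneric("mapperNodes", function(x) standardGeneric("mapperNodes"))

#' @rdname mapperAccessors
#' @export
setGeneric("mapperEdges", function(x) standardGeneric("mapperEdges"))

#' @rdname mapperAccessors
#' @export
setGeneric("nodeMembers", function(x) standardGeneric("nodeMembers"))

#' @rdname mapperAccessors
#' @export
setGeneric("noiseSamples", function(x) standardGeneric("noiseSamples"))

#' @rdname lensAccessors
#' @export
setGeneric("lensCenter", function(x) standardGeneric("lensCenter"))

#' @rdname lensAccessors
#' @export
setGeneric("lensBasis", function(x) standardGeneric("lensBasis"))

#' @rdname lensAccessors
#' @export
setGeneric("lensRank", function(x) standardGeneric("lensRank"))

#' @rdname coverAccessors
#' @export
setGeneric("coverIntervals", function(x) standardGeneric("coverIntervals"))

#' Mapper graph accessors
#'
#' @param x a \linkS4class{MapperGraph}.
#' @return \code{mapperNodes}: the node table; \code{mapperEdges}: the edge
#'   table; \code{nodeMembers}: named list of member sample ids per node;
#'   \code{noiseSamples}: samples excluded as DBSCAN noise.
#' @name mapperAccessors
NULL

setMethod("mapperNodes", "MapperGraph", function(x) x@nodes)
setMethod("mapperEdges", "MapperGraph", function(x) x@edges)
setMethod("nodeMembers", "MapperGraph", function(x) x@members)
setMethod("noiseSamples", "MapperGraph", function(x) x@noise)

#' Lens model accessors
#'
#' @param x a \linkS4class{LensModel}.
#' @return \code{lensCenter}: the mean vector; \code{lensBasis}: the
#'   orthonormal basis matrix; \code{lensRank}: the retained rank.
#' @name lensAccessors
NULL

setMethod("lensCenter", "LensModel", function(x) x@mu)
setMethod("lensBasis", "LensModel", function(x) x@basis)
setMethod("lensRank", "LensModel", function(x) x@rank)

#' Cover accessors
#'
#' @param x a \linkS4class{Cover}.
#' @return \code{coverIntervals}: numeric matrix of (lo, hi) interval bounds.
#' @name coverAccessors
NULL

setMethod("coverIntervals", "Cover", function(x) x@intervals)
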