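#' @name accessors
#' @title Accessors for RFsubtypes result objects
#'
#' @description Accessor generics for the S4 result classes:
#' \code{consensusFeatures} and \code{perForestSets} return the consensus
#' gene panel and the per-forest selected sets of a
#' \linkS4class{FeaturePanel}; \code{importanceMatrix} its genes x forests
#' importance matrix; \code{consensusMatrix} the expression data restricted
#' to the consensus genes. \code{lossTrace} returns the per-epoch training
#' losses of an \linkS4class{AutoencoderModel}. \code{clusterAssignments},
#' \code{clusterCentroids} and \code{clusterObjective} expose a
#' \linkS4class{KMeansModel}; \code{chosenK} the selected cluster number of
#' a \linkS4class{KSelection}.
#'
#' @param object a result object of the class documented above.
#' @return See the description per accessor.
NULL

#' @rdname accessors
#' @export
setGeneric("consensusFeatures",
           function(object) standardGeneric("consensusFeatures"))
#' @rdname accessors
#' @export
setGeneric("perForestSets",
           function(object) standardGeneric("perForestSets"))
#' @rdname accessors
#' @export
setGeneric("importanceMatrix",
           function(object) standardGeneric("importanceMatrix"))
#' @rdname accessors
#' @export
setGeneric("consensusMatrix",
           function(object) standardGeneric("consensusMatrix"))
#' @rdname accessors
#' @export
setGeneric("lossTrace", function(object) standardGeneric("lossTrace"))
#' @rdname accessors
#' @export
setGeneric("clusterAssignments",
           function(object) standardGeneric("clusterAssignments"))
#' @rdname accessors
#' @export
setGeneric("clusterCentroids",
           function(object) standardGeneric("clusterCentroids"))
#' @rdname accessors
#' @export
setGeneric("clusterObjective",
           function(object) standardGeneric("clusterObjective"))
#' @rdname accessors
#' @export
setGeneric("chosenK", function(object) standardGeneric("chosenK"))

#' @rdname accessors
#' @export
setMethod("consensusFeatures", "FeaturePanel",
          function(object) object@consensus)
#' @rdname accessors
#' @export
setMethod("perForestSets", "FeaturePanel",
          function(object) object@perForestSets)
#' @rdname accessors
#' @export
setMethod("importanceMatrix", "FeaturePanel",
          function(object) object@importances)
#' @rdname accessors
#' @export
setMethod("consensusMatrix", "FeaturePanel", function(object) object@xbar)
#' @rdname accessors
#' @export
setMethod("lossTrace", "AutoencoderModel", function(object) object@trace)
#' @rdname accessors
#' @export
setMethod("clusterAssignments", "KMeansModel",
          function(object) object@assignments)
#' @rdname accessors
#' @export
setMethod("clusterCentroids", "KMeansModel",
          function(object) object@centroids)
#' @rdname accessors
#' @export
setMethod("clusterObjective", "KMeansModel",
          function(object) object@objective)
#' @rdname accessors
#' @export
setMethod("chosenK", "KSelection", function(object) object@chosenK)
#' @rdname accessors
#' @export
setMethod("clusterAssignments", "KSelection",
          function(object) object@model@assignments)
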