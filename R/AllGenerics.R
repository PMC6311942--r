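#' @rdname InteractionNetwork-class
#' @param object,x an object.
#' @export
setGeneric("mirnaIds", function(x) standardGeneric("mirnaIds"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("lncrnaIds", function(x) standardGeneric("lncrnaIds"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("interactionPairs", function(x) standardGeneric("interactionPairs"))

#' Density of the observed bipartite network
#'
#' Returns the fraction of observed pairs among all nm x nl possible pairs,
#' together with the same value as a percentage.
#'
#' @param x an [InteractionNetwork-class] object.
#' @return named numeric vector with elements \code{fraction} and
#'   \code{percent}.
#' @examples
#' net <- InteractionNetwork(data.frame(mirna = c("m1", "m1", "m2"),
#'                                      lncrna = c("l1", "l2", "l1")))
#' networkDensity(net)
#' @export
setGeneric("networkDensity", function(x) standardGeneric("networkDensity"))

#' Mean number of lncRNA partners per miRNA
#'
#' @param x an [InteractionNetwork-class] object.
#' @return a single number, |pairs| / nm.
#' @export
setGeneric("averageMirnaDegree", function(x) standardGeneric("averageMirnaDegree"))

#' @rdname SimilarityMatrix-class
#' @param x an object.
#' @export
setGeneric("rnaIds", function(x) standardGeneric("rnaIds"))

#' @rdname SimilarityMatrix-class
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))

#' @rdname SimilarityMatrix-class
#' @export
setGeneric("similarityKind", function(x) standardGeneric("similarityKind"))

#' @rdname SimilarityMatrix-class
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname ExpressionProfileSet-class
#' @param x an object.
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname ExpressionProfileSet-class
#' @export
setGeneric("profileAvailable", function(x) standardGeneric("profileAvailable"))

#' @rdname GroupBPRModel-class
#' @param x an object.
#' @export
setGeneric("latentFactors", function(x) standardGeneric("latentFactors"))

#' @rdname GroupBPRModel-class
#' @export
setGeneric("itemBias", function(x) standardGeneric("itemBias"))

#' @rdname GroupBPRModel-class
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' @rdname CVResult-class
#' @param x an object.
#' @export
setGeneric("foldAUCs", function(x) standardGeneric("foldAUCs"))

#' @rdname CVResult-class
#' @export
setGeneric("meanAUC", function(x) standardGeneric("meanAUC"))

#' @rdname CVResult-class
#' @export
setGeneric("sdAUC", function(x) standardGeneric("sdAUC"))
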