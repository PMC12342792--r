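#' @rdname accessors
#' @export
setGeneric("factorLoadings", function(x) standardGeneric("factorLoadings"))

#' @rdname accessors
#' @export
setGeneric("factorScores", function(x) standardGeneric("factorScores"))

#' @rdname accessors
#' @export
setGeneric("scaledScores", function(x) standardGeneric("scaledScores"))

#' @rdname accessors
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))

#' @rdname accessors
#' @export
setGeneric("geneIntercepts", function(x) standardGeneric("geneIntercepts"))

#' @rdname accessors
#' @export
setGeneric("cellIntercepts", function(x) standardGeneric("cellIntercepts"))

#' @rdname accessors
#' @export
setGeneric("nFactors", function(x) standardGeneric("nFactors"))

#' @rdname accessors
#' @export
setGeneric("convergenceTrace", function(x) standardGeneric("convergenceTrace"))

#' @rdname accessors
#' @export
setGeneric("isProjected", function(x) standardGeneric("isProjected"))

#' @rdname meanMatrix
#' @export
setGeneric("meanMatrix", function(fit, ...) standardGeneric("meanMatrix"))

#' @rdname accessors
#' @export
setGeneric("scoreSE", function(x) standardGeneric("scoreSE"))

#' @rdname accessors
#' @export
setGeneric("loadingSE", function(x) standardGeneric("loadingSE"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname accessors
#' @export
setGeneric("cci", function(x) standardGeneric("cci"))

#' @rdname accessors
#' @export
setGeneric("interCCI", function(x) standardGeneric("interCCI"))

#' @rdname accessors
#' @export
setGeneric("nullThreshold", function(x) standardGeneric("nullThreshold"))
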