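#' Accessors for fitted objects
#'
#' Accessor functions for \code{\link{BilinearFit}}, \code{\link{FactorSE}},
#' \code{\link{CellClustering}} and \code{\link{CCIResult}} objects.
#' \code{factorScores} returns \code{V}; \code{scaledScores} returns
#' \code{V \%*\% diag(sigma)}, the representation usually plotted and the
#' one clustering operates on.
#'
#' @param x an object of the appropriate class.
#' @return The requested component.
#' @name accessors
#' @aliases factorLoadings factorScores scaledScores singularValues
#'   geneIntercepts cellIntercepts nFactors convergenceTrace isProjected
#'   scoreSE loadingSE clusterLabels nClusters cci interCCI nullThreshold
NULL

#' @rdname accessors
#' @export
setMethod("factorLoadings", "BilinearFit", function(x) x@U)

#' @rdname accessors
#' @export
setMethod("factorScores", "BilinearFit", function(x) x@V)

#' @rdname accessors
#' @export
setMethod("scaledScores", "BilinearFit", function(x) {
  if (length(x@sigma) == 0L) return(x@V)
  sweep(x@V, 2L, x@sigma, `*`)
})

#' @rdname accessors
#' @export
setMethod("singularValues", "BilinearFit", function(x) x@sigma)

#' @rdname accessors
#' @export
setMethod("geneIntercepts", "BilinearFit", function(x) x@alpha)

#' @rdname accessors
#' @export
setMethod("cellIntercepts", "BilinearFit", function(x) x@beta)

#' @rdname accessors
#' @export
setMethod("nFactors", "BilinearFit", function(x) length(x@sigma))

#' @rdname accessors
#' @export
setMethod("convergenceTrace", "BilinearFit", function(x) x@trace)

#' @rdname accessors
#' @export
setMethod("isProjected", "BilinearFit", function(x) x@projected)

setMethod("show", "BilinearFit", function(object) {
  cat(sprintf(
    "BilinearFit: %d genes x %d cells, M = %d factor%s%s\n",
    length(object@alpha), length(object@beta), length(object@sigma),
    if (length(object@sigma) == 1L) "" else "s",
    if (object@projected) " (projection method)" else ""
  ))
  if (length(object@sigma)) {
    cat("  sigma:", paste(signif(object@sigma, 4), collapse = " "), "\n")
  }
  cat(sprintf("  tau = %g; %d iterations; converged: %s\n",
    object@tau, length(object@trace), object@converged))
})

#' @rdname accessors
#' @export
setMethod("scoreSE", "FactorSE", function(x) x@seV)

#' @rdname accessors
#' @export
setMethod("loadingSE", "FactorSE", function(x) x@seU)

setMethod("show", "FactorSE", function(object) {
  cat(sprintf("FactorSE: score SEs for %d cells x %d factors",
    nrow(object@seV), ncol(object@seV)))
  if (nrow(object@seU)) cat(sprintf("; loading SEs for %d genes", nrow(object@seU)))
  cat("\n")
  if (any(object@singular))
    cat(sprintf("  %d singular Fisher block(s) (pseudo-inverse used)\n",
      sum(object@singular)))
})

#' @rdname accessors
#' @export
setMethod("clusterLabels", "CellClustering", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("nClusters", "CellClustering", function(x) x@K)

setMethod("show", "CellClustering", function(object) {
  cat(sprintf("CellClustering: %d cells in %d clusters (%s)\n",
    length(object@labels), object@K, object@method))
})

#' @rdname accessors
#' @export
setMethod("cci", "CCIResult", function(x) x@cci)

#' @rdname accessors
#' @export
setMethod("interCCI", "CCIResult", function(x) x@interCCI)

#' @rdname accessors
#' @export
setMethod("nullThreshold", "CCIResult", function(x) x@nullThreshold)

setMethod("show", "CCIResult", function(object) {
  cat(sprintf("CCIResult: %d clusters, %d repetitions\n",
    length(object@cci), object@nReps))
  cat("  CCI:", paste(signif(object@cci, 3), collapse = " "), "\n")
  if (!is.na(object@nullThreshold))
    cat(sprintf("  null threshold: %.3f\n", object@nullThreshold))
})
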