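#' @import methods
NULL

#' BilinearFit: a fitted Poisson bilinear model
#'
#' Container for the parameters of the Poisson generalized bilinear model
#' \deqn{Y_{ij} \sim \mathrm{Poisson}(\mu_{ij}), \quad
#'   \log \mu_{ij} = \alpha_i + \beta_j + \sum_{m=1}^M \sigma_m u_{im} v_{jm},}
#' where \eqn{\alpha} are gene intercepts, \eqn{\beta} are cell intercepts,
#' and the interaction \eqn{X = U \Sigma V^T} is a rank-\eqn{M} matrix in
#' canonical (SVD) form.
#'
#' Canonical form means \eqn{U^T U = V^T V = I_M}, the singular values
#' \code{sigma} are positive and non-increasing, and for each factor the
#' largest-magnitude entry of the corresponding column of \code{U} is
#' positive. Fits produced by the projection method
#' (\code{\link{fitGBMProjected}}) carry per-cell GLM estimates of the
#' scores, so \code{V} is not exactly orthonormal; such fits have
#' \code{projected = TRUE} and validity relaxes the orthonormality check
#' on \code{V}.
#'
#' @slot alpha numeric, length-I gene intercepts (natural-log scale).
#' @slot beta numeric, length-J cell intercepts (natural-log scale).
#' @slot U I x M matrix of factor loadings, orthonormal columns.
#' @slot sigma numeric, length-M positive non-increasing singular values.
#' @slot V J x M matrix of factor scores.
#' @slot tau non-negative rate of the Exponential prior on the singular
#'   values (the nuclear-norm penalty weight).
#' @slot trace numeric vector of per-iteration penalized log-posterior
#'   values recorded during fitting.
#' @slot converged logical, whether the fitting loop met its tolerance.
#' @slot projected logical, TRUE for projection-method fits.
#'
#' @seealso \code{\link{fitGBM}}, \code{\link{meanMatrix}},
#'   \code{\link{scoreStandardErrors}}
#' @export
setClass("BilinearFit",
  representation(
    alpha = "numeric",
    beta = "numeric",
    U = "matrix",
    sigma = "numeric",
    V = "matrix",
    tau = "numeric",
    trace = "numeric",
    converged = "logical",
    projected = "logical"
  ),
  prototype(
    tau = 0, trace = numeric(0), converged = TRUE, projected = FALSE
  )
)

.ORTHO_TOL <- 1e-8

.checkOrthonormal <- function(A, what, tol = .ORTHO_TOL) {
  if (ncol(A) == 0L) return(NULL)
  G <- crossprod(A)
  if (max(abs(G - diag(ncol(A)))) > tol) {
    return(sprintf("columns of %s are not orthonormal (tol %g)", what, tol))
  }
  NULL
}

setValidity("BilinearFit", function(object) {
  msg <- character(0)
  I <- length(object@alpha)
  J <- length(object@beta)
  M <- length(object@sigma)
  if (nrow(object@U) != I || ncol(object@U) != M)
    msg <- c(msg, sprintf("U must be %d x %d", I, M))
  if (nrow(object@V) != J || ncol(object@V) != M)
    msg <- c(msg, sprintf("V must be %d x %d", J, M))
  if (M > 0) {
    if (any(object@sigma <= 0))
      msg <- c(msg, "all sigma must be > 0 (zero components are dropped)")
    if (is.unsorted(rev(object@sigma)))
      msg <- c(msg, "sigma must be non-increasing")
    m1 <- .checkOrthonormal(object@U, "U")
    if (!is.null(m1)) msg <- c(msg, m1)
    if (!object@projected) {
      m2 <- .checkOrthonormal(object@V, "V")
      if (!is.null(m2)) msg <- c(msg, m2)
    }
  }
  if (length(object@tau) != 1L || object@tau < 0)
    msg <- c(msg, "tau must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' FactorSE: standard errors for latent factor coordinates
#'
#' Per-entry standard errors for the factor scores \code{V} (and optionally
#' the loadings \code{U}) of a \code{\link{BilinearFit}}, obtained from the
#' diagonal blocks of the Fisher information. These are level-free raw
#' standard errors; they understate the true uncertainty because the other
#' parameters are treated as fixed.
#'
#' @slot seV J x M matrix of standard errors for the entries of V.
#' @slot seU I x M matrix of standard errors for the entries of U (may be
#'   a 0 x M matrix when not computed).
#' @slot singular logical vector flagging cells whose Fisher block was
#'   numerically singular (pseudo-inverse used).
#'
#' @seealso \code{\link{scoreStandardErrors}}
#' @export
setClass("FactorSE",
  representation(seV = "matrix", seU = "matrix", singular = "logical"),
  prototype(seU = matrix(0, 0, 0), singular = logical(0))
)

setValidity("FactorSE", function(object) {
  if (any(!is.finite(object@seV)) || any(object@seV <= 0))
    return("all score standard errors must be finite and > 0")
  TRUE
})

#' CellClustering: a clustering of cells with its method descriptor
#'
#' Holds integer cluster labels (1..K) for J cells together with the
#' parameters that produced them, so the identical procedure can be
#' re-applied to perturbed scores when computing cluster cohesion indices.
#'
#' @slot labels integer vector of length J with values in 1..K.
#' @slot K integer, number of clusters.
#' @slot method character, clustering backend ("louvain" or "kmeans").
#' @slot params list of backend parameters (e.g. k, resolution, seed,
#'   centers).
#'
#' @seealso \code{\link{clusterCells}}, \code{\link{computeCCI}}
#' @export
setClass("CellClustering",
  representation(
    labels = "integer", K = "integer", method = "character", params = "list"
  )
)

setValidity("CellClustering", function(object) {
  msg <- character(0)
  if (object@K < 1L) msg <- c(msg, "K must be >= 1")
  if (any(object@labels < 1L | object@labels > object@K))
    msg <- c(msg, "labels must lie in 1..K")
  if (length(msg)) msg else TRUE
})

#' CCIResult: cluster cohesion indices
#'
#' Per-cluster cluster cohesion indices (CCI), the pairwise inter-cluster
#' cohesion matrix, and the resampling parameters. All values lie in
#' [0, 1]; the diagonal of \code{interCCI} equals \code{cci} by
#' construction. Singleton clusters have no within-cluster pairs and are
#' reported as \code{NA}.
#'
#' @slot cci numeric length-K per-cluster CCI.
#' @slot interCCI K x K symmetric matrix of inter-cluster cohesion
#'   indices, diagonal equal to \code{cci}.
#' @slot nullThreshold numeric, null significance threshold (NA until
#'   computed with \code{\link{cciNullThreshold}}).
#' @slot nReps integer, number of perturbation repetitions.
#'
#' @seealso \code{\link{computeCCI}}
#' @export
setClass("CCIResult",
  representation(
    cci = "numeric", interCCI = "matrix", nullThreshold = "numeric",
    nReps = "integer"
  ),
  prototype(nullThreshold = NA_real_)
)

setValidity("CCIResult", function(object) {
  msg <- character(0)
  K <- length(object@cci)
  if (!all(dim(object@interCCI) == c(K, K)))
    msg <- c(msg, "interCCI must be K x K")
  vals <- c(object@cci, object@interCCI)
  vals <- vals[!is.na(vals)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 1))
    msg <- c(msg, "all CCI values must lie in [0, 1]")
  d <- diag(object@interCCI)
  same <- (is.na(d) & is.na(object@cci)) |
    (!is.na(d) & !is.na(object@cci) & d == object@cci)
  if (!all(same))
    msg <- c(msg, "diagonal of interCCI must equal cci")
  if (length(msg)) msg else TRUE
})
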