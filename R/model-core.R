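#' @importFrom stats rnorm rpois rbinom qnorm quantile kmeans dist glm
#'   poisson coef optim
#' @importFrom utils read.delim write.table
NULL

# ---- count-matrix validation -------------------------------------------

#' Validate a genes x cells count matrix
#'
#' Checks that a matrix of UMI counts is numeric, non-negative and integral,
#' and returns it as a base dense matrix with gene and cell identifiers in
#' the dimnames (generated if absent). Sparse \code{Matrix} inputs are
#' densified; the fitting algorithm operates on dense working matrices
#' anyway.
#'
#' @param Y matrix or sparse Matrix of counts, genes on rows.
#' @return dense numeric matrix with dimnames.
#' @export
validateCounts <- function(Y) {
  if (is(Y, "Matrix")) Y <- as.matrix(Y)
  if (!is.matrix(Y) || !is.numeric(Y))
    stop("counts must be a numeric matrix (genes x cells)")
  if (nrow(Y) < 1L || ncol(Y) < 1L)
    stop("count matrix must have at least one gene and one cell")
  bad <- which(!is.finite(Y) | Y < 0 | Y != round(Y), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "counts must be non-negative integers; first offender at gene %d, cell %d (value %g)",
      bad[1, 1], bad[1, 2], Y[bad[1, 1], bad[1, 2]]))
  }
  if (is.null(rownames(Y))) rownames(Y) <- paste0("gene", seq_len(nrow(Y)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("cell", seq_len(ncol(Y)))
  Y
}

#' Drop all-zero genes and cells
#'
#' Genes with zero total count and cells with zero library size have
#' intercept MLEs at minus infinity and must be removed before fitting.
#' \code{filterZeroMargins} drops them with a message;
#' \code{checkMargins} errors instead.
#'
#' @param Y count matrix, genes x cells.
#' @return Filtered count matrix.
#' @export
filterZeroMargins <- function(Y) {
  Y <- validateCounts(Y)
  rz <- rowSums(Y) == 0
  cz <- colSums(Y) == 0
  if (any(rz)) message(sum(rz), " all-zero gene(s) removed")
  if (any(cz)) message(sum(cz), " zero-count cell(s) removed")
  Y <- Y[!rz, !cz, drop = FALSE]
  if (nrow(Y) < 1L || ncol(Y) < 1L)
    stop("no genes or cells left after zero-margin filtering")
  Y
}

#' @rdname filterZeroMargins
#' @export
checkMargins <- function(Y) {
  if (any(rowSums(Y) == 0))
    stop("genes with all-zero counts present; use filterZeroMargins()")
  if (any(colSums(Y) == 0))
    stop("cells with zero total count present; use filterZeroMargins()")
  invisible(Y)
}

# ---- construction and the mean matrix ----------------------------------

.newFit <- function(alpha, beta, U, sigma, V, tau = 0, trace = numeric(0),
                    converged = TRUE, projected = FALSE, validate = TRUE) {
  obj <- new("BilinearFit",
    alpha = as.numeric(alpha), beta = as.numeric(beta),
    U = U, sigma = as.numeric(sigma), V = V, tau = tau,
    trace = trace, converged = converged, projected = projected)
  if (validate) validObject(obj)
  obj
}

# low-rank interaction X = U diag(sigma) V^T as a dense I x J matrix
.interaction <- function(fit) {
  I <- length(fit@alpha); J <- length(fit@beta)
  if (length(fit@sigma) == 0L) return(matrix(0, I, J))
  tcrossprod(sweep(fit@U, 2L, fit@sigma, `*`), fit@V)
}

.linearPredictor <- function(fit, X = NULL) {
  if (is.null(X)) X <- .interaction(fit)
  X + fit@alpha + rep(fit@beta, each = length(fit@alpha))
}

#' Fitted Poisson means of a bilinear model
#'
#' Computes \eqn{\mu_{ij} = \exp(\alpha_i + \beta_j + \sum_m \sigma_m
#' u_{im} v_{jm})}. Linear predictors above \code{cap} (natural-log scale)
#' indicate overflow and raise an error naming the offending entry.
#'
#' @param fit a \code{\link{BilinearFit}}.
#' @param cap numeric cap on the linear predictor; default 30.
#' @param ... unused.
#' @return I x J matrix of positive means.
#' @export
setMethod("meanMatrix", "BilinearFit", function(fit, cap = 30, ...) {
  eta <- .linearPredictor(fit)
  if (any(eta > cap)) {
    bad <- which(eta > cap, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "linear predictor exceeds cap %g at gene %d, cell %d (value %.2f)",
      cap, bad[1], bad[2], eta[bad[1], bad[2]]))
  }
  exp(eta)
})

# ---- likelihood and posterior ------------------------------------------

#' Poisson log-likelihood and log-posterior
#'
#' \code{logLikGBM} returns the Poisson log-likelihood with additive
#' constants (the \eqn{-\log Y_{ij}!} terms) removed:
#' \eqn{\sum_{ij} (Y_{ij} \log \mu_{ij} - \mu_{ij})}.
#' \code{logPosteriorGBM} subtracts the Exponential prior penalty
#' \eqn{\tau \sum_m \sigma_m} (the nuclear norm of the interaction scaled
#' by \code{tau}), again up to additive constants.
#'
#' @param Y count matrix, genes x cells.
#' @param fit a \code{\link{BilinearFit}} with matching dimensions.
#' @param cap linear-predictor overflow cap passed to
#'   \code{\link{meanMatrix}}.
#' @return a single number.
#' @export
logLikGBM <- function(Y, fit, cap = 30) {
  if (nrow(Y) != length(fit@alpha) || ncol(Y) != length(fit@beta))
    stop("dimensions of Y and fit do not agree")
  eta <- .linearPredictor(fit)
  if (any(eta > cap))
    stop(sprintf("linear predictor exceeds cap %g", cap))
  sum(Y * eta) - sum(exp(eta))
}

#' @rdname logLikGBM
#' @export
logPosteriorGBM <- function(Y, fit, cap = 30) {
  logLikGBM(Y, fit, cap = cap) - fit@tau * sum(fit@sigma)
}

# ---- canonicalization ---------------------------------------------------

#' Canonical parameterization of a bilinear fit
#'
#' Re-expresses an arbitrary factorization \code{U_raw diag(sigma_raw)
#' V_raw^T} in canonical form: orthonormal \code{U} and \code{V},
#' positive non-increasing \code{sigma} (zero singular values dropped with
#' a warning), and the sign convention that each loading column's
#' largest-magnitude entry is positive. The implied mean matrix is
#' preserved exactly (up to floating point).
#'
#' @param alpha,beta intercept vectors.
#' @param U_raw,V_raw factor matrices (full column rank).
#' @param sigma_raw non-negative scale factors.
#' @param tau prior rate carried into the result.
#' @param trace,converged,projected metadata carried into the result.
#' @return a \code{\link{BilinearFit}} in canonical form.
#' @export
canonicalizeFit <- function(alpha, beta, U_raw, sigma_raw, V_raw, tau = 0,
                            trace = numeric(0), converged = TRUE,
                            projected = FALSE) {
  I <- length(alpha); J <- length(beta)
  M <- length(sigma_raw)
  if (M == 0L) {
    return(.newFit(alpha, beta, matrix(0, I, 0), numeric(0),
      matrix(0, J, 0), tau, trace, converged, projected))
  }
  if (any(sigma_raw < 0)) stop("sigma_raw must be non-negative")
  qu <- qr(U_raw); qv <- qr(V_raw)
  if (qu$rank < M || qv$rank < M)
    stop("factor matrices are rank deficient")
  # small M x M core carries all the non-orthogonality
  core <- qr.R(qu) %*% (sigma_raw * t(qr.R(qv)))
  s <- svd(core)
  keep <- s$d > max(s$d[1], 1) * .Machine$double.eps * 100
  if (!all(keep)) warning(sum(!keep), " zero singular value(s) dropped")
  U <- qr.Q(qu) %*% s$u[, keep, drop = FALSE]
  V <- qr.Q(qv) %*% s$v[, keep, drop = FALSE]
  sigma <- s$d[keep]
  fixed <- .fixSigns(U, V)
  .newFit(alpha, beta, fixed$U, sigma, fixed$V, tau, trace, converged,
    projected)
}

# sign convention: largest-|entry| of each U column positive
.fixSigns <- function(U, V) {
  for (m in seq_len(ncol(U))) {
    i <- which.max(abs(U[, m]))
    if (U[i, m] < 0) {
      U[, m] <- -U[, m]
      V[, m] <- -V[, m]
    }
  }
  list(U = U, V = V)
}
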