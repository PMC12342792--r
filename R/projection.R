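# Subsample-and-project fitting: estimate (alpha, U, Sigma) on a random
# subset of cells, then fit each cell's intercept and scores by an
# independent Poisson GLM with design [1, U] and offset alpha. Columns are
# processed one at a time, so memory stays bounded in J.

#' Randomly subsample cells
#'
#' Uniform sampling of cell columns without replacement; the selected
#' index set is returned for reproducibility.
#'
#' @param Y count matrix, genes x cells.
#' @param nSub number of cells to keep (1..J).
#' @param seed optional integer seed.
#' @return list with \code{Y} (the subset) and \code{idx} (sorted column
#'   indices).
#' @export
subsampleCells <- function(Y, nSub, seed = NULL) {
  J <- ncol(Y)
  if (nSub < 1L || nSub > J) stop("nSub must be in 1..", J)
  if (!is.null(seed)) withr::local_seed(seed)
  idx <- sort(sample.int(J, nSub))
  list(Y = Y[, idx, drop = FALSE], idx = idx)
}

#' Fit one cell's intercept and scores by Poisson IRLS
#'
#' With \code{alpha}, \code{U} and \code{sigma} frozen, column j of the
#' bilinear model is a Poisson GLM for the counts \code{y} with covariate
#' matrix \code{U}, coefficients \eqn{(\beta_j, \gamma_{j1}, \ldots,
#' \gamma_{jM})} where \eqn{\gamma_{jm} = \sigma_m v_{jm}}, and offset
#' \code{alpha}. Fit by iteratively reweighted least squares (at most
#' \code{maxIter} steps, tolerance \code{tol} on the coefficient change).
#'
#' @param y length-I count vector (one cell).
#' @param alpha gene intercepts (offset).
#' @param U I x M orthonormal loadings.
#' @param sigma length-M positive singular values.
#' @param maxIter,tol IRLS controls.
#' @param cap linear-predictor cap.
#' @return list with \code{beta} (scalar), \code{v} (length-M scores,
#'   \eqn{v_{jm} = \gamma_{jm}/\sigma_m}), and \code{converged}.
#' @export
fitCellGLM <- function(y, alpha, U, sigma, maxIter = 25, tol = 1e-8,
                       cap = 30) {
  if (sum(y) == 0) stop("cell has zero total count")
  M <- length(sigma)
  D <- cbind(1, U)
  # margin-matched start: beta from the intercept-only model
  theta <- c(log(sum(y)) - log(sum(exp(alpha))), rep(0, M))
  best <- theta; bestll <- -Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    eta <- pmin(alpha + drop(D %*% theta), cap)
    mu <- exp(eta)
    ll <- sum(y * eta - mu)
    if (ll > bestll) {
      bestll <- ll
      best <- theta
    }
    z <- eta - alpha + (y - mu) / mu   # working response minus offset
    W <- mu
    XtW <- t(D * W)
    thetaNew <- tryCatch(
      solve(XtW %*% D, XtW %*% z),
      error = function(e) NULL)
    if (is.null(thetaNew) || any(!is.finite(thetaNew))) break
    delta <- max(abs(thetaNew - theta))
    theta <- drop(thetaNew)
    if (delta < tol) {
      converged <- TRUE
      # record the converged point if it improves the likelihood
      eta <- pmin(alpha + drop(D %*% theta), cap)
      ll <- sum(y * eta - exp(eta))
      if (ll > bestll) best <- theta
      break
    }
  }
  if (!converged) theta <- best
  list(beta = theta[1], v = theta[-1] / sigma, converged = converged)
}

#' Fit a bilinear model by subsampling and projection
#'
#' Runs \code{\link{fitGBM}} on a random subset of cells, freezes the gene
#' intercepts, loadings and singular values, and fits every cell
#' (including subset cells, so all scores have a single provenance) by an
#' independent per-cell Poisson GLM via \code{\link{fitCellGLM}}. The
#' returned scores are per-cell maximum-likelihood estimates, so \code{V}
#' is not re-orthonormalized; the fit is flagged \code{projected}.
#'
#' @param Y count matrix with positive margins.
#' @param M number of latent factors.
#' @param nSub subset size (must be at least M + 2).
#' @param seed integer seed controlling the subsample.
#' @param keepSubsetScores if TRUE, cells in the subset keep their scores
#'   from the subset fit instead of being refit.
#' @param tau,maxIter,tol,cap,centerFactors passed to \code{\link{fitGBM}}.
#' @return a \code{\link{BilinearFit}} with \code{projected = TRUE}.
#' @export
fitGBMProjected <- function(Y, M, nSub, seed = NULL, tau = 0,
                            maxIter = 100, tol = 1e-6, cap = 30,
                            centerFactors = TRUE,
                            keepSubsetScores = FALSE) {
  Y <- validateCounts(Y)
  checkMargins(Y)
  if (nSub < M + 2) stop("nSub must be at least M + 2")
  sub <- subsampleCells(Y, nSub, seed = seed)
  subFit <- fitGBM(sub$Y, M = M, tau = tau, maxIter = maxIter, tol = tol,
    cap = cap, centerFactors = centerFactors)
  Msub <- nFactors(subFit)
  alpha <- geneIntercepts(subFit)
  U <- factorLoadings(subFit)
  sigma <- singularValues(subFit)
  J <- ncol(Y)
  beta <- numeric(J)
  V <- matrix(0, J, Msub)
  conv <- logical(J)
  for (j in seq_len(J)) {
    if (keepSubsetScores && j %in% sub$idx) {
      pos <- match(j, sub$idx)
      beta[j] <- cellIntercepts(subFit)[pos]
      V[j, ] <- factorScores(subFit)[pos, ]
      conv[j] <- TRUE
      next
    }
    cf <- fitCellGLM(Y[, j], alpha, U, sigma, cap = cap)
    beta[j] <- cf$beta
    V[j, ] <- cf$v
    conv[j] <- cf$converged
  }
  if (any(!conv))
    warning(sum(!conv), " cell(s) did not converge in per-cell IRLS")
  out <- .newFit(alpha, beta, U, sigma, V, tau = tau,
    trace = convergenceTrace(subFit), converged = subFit@converged,
    projected = TRUE)
  dimnames(out@V) <- list(colnames(Y), NULL)
  names(out@beta) <- colnames(Y)
  out
}
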