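# Block Fisher-information standard errors for factor scores. The block
# for cell j is F_j = (U Sigma)^T diag(mu_.j) (U Sigma), the negative
# expected Hessian of the Poisson log-likelihood in v_j with all other
# parameters fixed. Standard errors are sqrt(diag(F_j^{-1})); they
# understate the uncertainty because alpha, beta, U and Sigma are treated
# as known.

#' Fisher information block for one cell's scores
#'
#' @param U I x M orthonormal loadings.
#' @param sigma length-M positive singular values.
#' @param muCol length-I vector of Poisson means for the cell.
#' @return M x M symmetric positive semi-definite matrix
#'   \eqn{(U\Sigma)^T \mathrm{diag}(\mu_{\cdot j}) (U\Sigma)}.
#' @export
fisherBlock <- function(U, sigma, muCol) {
  if (length(muCol) != nrow(U)) stop("muCol length must match nrow(U)")
  if (length(sigma) != ncol(U)) stop("sigma length must match ncol(U)")
  if (any(sigma <= 0)) stop("sigma must be positive")
  A <- sweep(U, 2L, sigma, `*`)
  crossprod(A, muCol * A)
}

#' Standard errors for factor scores (and loadings)
#'
#' Computes, for every cell j, \eqn{\mathrm{se}(\hat v_{jm}) =
#' \sqrt{[F_j^{-1}]_{mm}}} with \eqn{F_j} the Fisher block at the fitted
#' means. Loadings are handled in the complementary way:
#' \eqn{G_i = (V\Sigma)^T \mathrm{diag}(\mu_{i\cdot}) (V\Sigma)}.
#' Numerically singular blocks fall back to the Moore-Penrose
#' pseudo-inverse with a warning and are flagged. These block standard
#' errors underestimate the true uncertainty (the other parameters are
#' plugged in as fixed).
#'
#' @param fit a \code{\link{BilinearFit}} with at least one factor.
#' @param mu optional precomputed mean matrix (saves one evaluation).
#' @param loadings if TRUE also compute standard errors for U.
#' @param cap linear-predictor cap for the mean evaluation.
#' @return a \code{\link{FactorSE}}.
#' @export
scoreStandardErrors <- function(fit, mu = NULL, loadings = FALSE, cap = 30) {
  M <- nFactors(fit)
  if (M == 0L) stop("fit has no factors; no score uncertainty to compute")
  if (is.null(mu)) mu <- meanMatrix(fit, cap = cap)
  seV <- .blockSE(fit@U, fit@sigma, mu)
  seU <- if (loadings) .blockSE(fit@V, fit@sigma, t(mu)) else
    matrix(0, 0, M)
  singular <- attr(seV, "singular")
  if (any(singular))
    warning(sum(singular),
      " cell(s) had singular Fisher blocks; pseudo-inverse used")
  attr(seV, "singular") <- NULL
  rownames(seV) <- names(fit@beta)
  if (loadings) {
    attr(seU, "singular") <- NULL
    rownames(seU) <- names(fit@alpha)
  }
  new("FactorSE", seV = seV, seU = seU, singular = singular)
}

# per-column Fisher blocks of A = U Sigma against the columns of mu
.blockSE <- function(U, sigma, mu) {
  A <- sweep(U, 2L, sigma, `*`)
  M <- ncol(A)
  J <- ncol(mu)
  # F_j[m, m'] = sum_i A[i,m] A[i,m'] mu[i,j]: one crossprod per (m, m') pair
  Fall <- array(0, c(M, M, J))
  for (m in seq_len(M)) {
    for (mp in m:M) {
      f <- drop(crossprod(mu, A[, m] * A[, mp]))
      Fall[m, mp, ] <- f
      Fall[mp, m, ] <- f
    }
  }
  se <- matrix(NA_real_, J, M)
  singular <- logical(J)
  for (j in seq_len(J)) {
    Fj <- Fall[, , j, drop = FALSE]
    dim(Fj) <- c(M, M)
    inv <- tryCatch(chol2inv(chol(Fj)), error = function(e) NULL)
    if (is.null(inv)) {
      inv <- MASS::ginv(Fj)
      singular[j] <- TRUE
    }
    se[j, ] <- sqrt(pmax(diag(inv), 0))
  }
  attr(se, "singular") <- singular
  se
}

#' Normal-theory confidence intervals for factor scores
#'
#' @param fit a \code{\link{BilinearFit}}.
#' @param se a \code{\link{FactorSE}} for the fit.
#' @param level confidence level in (0, 1).
#' @return list with J x M matrices \code{lower} and \code{upper}:
#'   \eqn{\hat v_{jm} \pm z_{(1+\mathrm{level})/2}\,\mathrm{se}_{jm}}.
#' @export
confidenceIntervals <- function(fit, se, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  z <- qnorm((1 + level) / 2)
  V <- factorScores(fit)
  s <- scoreSE(se)
  if (!all(dim(V) == dim(s))) stop("fit and se dimensions do not agree")
  list(lower = V - z * s, upper = V + z * s)
}
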