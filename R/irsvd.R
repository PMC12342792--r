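# Iteratively reweighted SVD for the Poisson bilinear model.
#
# One outer iteration: (1) form the working matrix X + (Y - mu)/mu_max,
# which equals X + W o (Z - X) for the IRLS weights W = mu/mu_max and
# working response Z = X + (Y - mu)/mu; (2) replace X by its rank-M
# truncated SVD with singular values soft-thresholded by tau; (3) update
# the gene and cell intercepts to their closed-form conditional MLEs.

#' Initialize a bilinear fit from the count margins
#'
#' Starts from the intercept-only (M = 0) model whose means are the
#' margin product \eqn{(\mathrm{rowsum}_i)(\mathrm{colsum}_j)/\mathrm{total}}:
#' \eqn{\beta_j = \log S_j - \overline{\log S}} with \eqn{S_j} the library
#' size of cell j, and \eqn{\alpha_i} its conditional closed form. This is
#' the same base model that underlies analytic Pearson residuals.
#'
#' @param Y count matrix with positive margins.
#' @param tau prior rate to carry into the fit.
#' @return a \code{\link{BilinearFit}} with no factors.
#' @export
initializeFit <- function(Y, tau = 0) {
  checkMargins(Y)
  S <- colSums(Y)
  beta <- log(S) - mean(log(S))
  alpha <- log(rowSums(Y)) - log(sum(exp(beta)))
  .newFit(alpha, beta, matrix(0, nrow(Y), 0), numeric(0),
    matrix(0, ncol(Y), 0), tau = tau)
}

#' Soft-thresholded truncated SVD
#'
#' Rank-\code{M} truncated singular value decomposition of \code{A} with
#' each retained singular value replaced by \eqn{\max(s_m - \tau, 0)}
#' (the proximal operator of the nuclear norm); components thresholded to
#' zero are dropped. Output satisfies the canonical sign convention.
#'
#' @param A numeric matrix with finite entries.
#' @param M maximum rank retained.
#' @param tau soft-threshold amount (>= 0).
#' @return list with components \code{U}, \code{sigma}, \code{V}.
#' @export
svdSoftThreshold <- function(A, M, tau = 0) {
  if (any(!is.finite(A))) stop("A must have finite entries")
  M <- min(M, nrow(A) - 0L, ncol(A))
  if (M <= 0L) {
    return(list(U = matrix(0, nrow(A), 0), sigma = numeric(0),
      V = matrix(0, ncol(A), 0)))
  }
  s <- svd(A, nu = M, nv = M)
  d <- pmax(s$d[seq_len(M)] - tau, 0)
  keep <- d > 0
  U <- s$u[, keep, drop = FALSE]
  V <- s$v[, keep, drop = FALSE]
  fixed <- .fixSigns(U, V)
  list(U = fixed$U, sigma = d[keep], V = fixed$V)
}

# Truncated SVD with optional warm start. Small problems (or a cold
# start) use LAPACK directly; large ones use subspace iteration on the
# previous iterate's row basis, which is accurate here because the
# working matrix changes slowly between outer iterations and any residual
# inexactness is corrected by later iterations (the objective is
# monitored either way).
.truncSVD <- function(A, M, warm = NULL, exactDim = 120, power = 2L) {
  k <- min(M + 4L, dim(A))
  Mk <- min(M, k)
  if (is.null(warm) || min(dim(A)) <= exactDim || ncol(warm) < k) {
    s <- svd(A, nu = Mk, nv = k)
    return(list(u = s$u, d = s$d[seq_len(Mk)],
      v = s$v[, seq_len(Mk), drop = FALSE], basis = s$v))
  }
  V0 <- warm[, seq_len(k), drop = FALSE]
  for (p in seq_len(power)) {
    Q <- qr.Q(qr(A %*% V0))
    V0 <- qr.Q(qr(crossprod(A, Q)))
  }
  B <- A %*% V0                  # I x k
  sb <- svd(B)
  list(u = sb$u[, seq_len(min(M, k)), drop = FALSE],
    d = sb$d[seq_len(min(M, k))],
    v = (V0 %*% sb$v)[, seq_len(min(M, k)), drop = FALSE],
    basis = V0 %*% sb$v)
}

# double-center a matrix; returns centered matrix plus the absorbed
# row/column mean components
.doubleCenter <- function(A) {
  g <- mean(A)
  r <- rowMeans(A) - g
  cc <- colMeans(A) - g
  list(Ac = A - outer(r, rep(1, ncol(A))) - rep(cc, each = nrow(A)) - g,
    row = r + g, col = cc)
}

#' One working-matrix update of the low-rank interaction
#'
#' Replaces the interaction \eqn{X} of \code{fit} by the soft-thresholded
#' truncated SVD of the working matrix \eqn{X + (Y - \hat\mu)/\hat\mu_*},
#' where \eqn{\hat\mu_* = \max_{ij} \hat\mu_{ij}}. With
#' \code{centerFactors = TRUE} the working matrix is doubly centered first
#' and the removed row/column means are absorbed into the intercepts,
#' which removes the gauge freedom between the intercepts and the factors;
#' with \code{FALSE} the intercepts are untouched.
#'
#' @param Y count matrix.
#' @param fit current \code{\link{BilinearFit}}.
#' @param M target rank.
#' @param tau soft-threshold amount.
#' @param cap linear-predictor cap.
#' @param centerFactors logical; see Details.
#' @return an updated \code{\link{BilinearFit}} (not yet intercept-refit).
#' @export
workingUpdate <- function(Y, fit, M = nFactors(fit), tau = fit@tau,
                          cap = 30, centerFactors = TRUE) {
  wm <- .workingMatrix(Y, fit, cap = cap, centerFactors = centerFactors)
  udv <- svdSoftThreshold(wm$A, M, tau)
  .newFit(wm$alpha, wm$beta, udv$U, udv$sigma, udv$V, tau = fit@tau,
    trace = fit@trace, converged = fit@converged, validate = FALSE)
}

# working matrix X + (Y - mu)/mu_max and (possibly mean-absorbing)
# intercepts shared by workingUpdate and the fitGBM loop
.workingMatrix <- function(Y, fit, cap = 30, centerFactors = TRUE) {
  X <- .interaction(fit)
  mu <- exp(.capCheck(X + fit@alpha + rep(fit@beta, each = nrow(X)), cap))
  mustar <- max(mu)
  A <- X + (Y - mu) / mustar
  alpha <- fit@alpha; beta <- fit@beta
  if (centerFactors) {
    dc <- .doubleCenter(A)
    A <- dc$Ac
    alpha <- alpha + dc$row
    beta <- beta + dc$col
  }
  list(A = A, alpha = alpha, beta = beta)
}

.capCheck <- function(eta, cap) {
  if (any(eta > cap)) {
    bad <- which(eta > cap, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "linear predictor exceeds cap %g at gene %d, cell %d",
      cap, bad[1], bad[2]))
  }
  eta
}

#' Closed-form intercept updates
#'
#' With the interaction fixed, the conditional MLEs of the gene and cell
#' intercepts are available in closed form and all entries of each vector
#' can be updated simultaneously: first
#' \eqn{\alpha_i \gets \log \sum_j Y_{ij} - \log \sum_j e^{\beta_j + X_{ij}}},
#' then the symmetric update of \eqn{\beta} using the new \eqn{\alpha}.
#' Each sweep cannot decrease the log-likelihood at fixed \eqn{X}.
#'
#' @inheritParams workingUpdate
#' @return an updated \code{\link{BilinearFit}}.
#' @export
updateIntercepts <- function(Y, fit, cap = 30) {
  checkMargins(Y)
  X <- .interaction(fit)
  Eb <- exp(.capCheck(X + rep(fit@beta, each = nrow(X)), cap))
  alpha <- log(rowSums(Y)) - log(rowSums(Eb))
  Ea <- exp(.capCheck(X + alpha, cap))
  beta <- log(colSums(Y)) - log(colSums(Ea))
  .newFit(alpha, beta, fit@U, fit@sigma, fit@V, tau = fit@tau,
    trace = fit@trace, converged = fit@converged, validate = FALSE)
}

#' Fit a Poisson bilinear model by iteratively reweighted SVD
#'
#' Alternates soft-thresholded truncated SVD updates of the low-rank
#' interaction with closed-form intercept updates, starting from the
#' margin-based intercept-only model, until the relative change of the
#' penalized log-posterior falls below \code{tol} or \code{maxIter} is
#' reached. The SVD surrogate step is not guaranteed to be an ascent step,
#' so the objective is monitored: if an iteration decreases it by more
#' than 1e-8, the interaction step is halved (convex combination of old
#' and new, re-truncated to rank M) up to 5 times, and the best iterate
#' seen is returned. Deterministic given \code{Y} and the configuration.
#'
#' @param Y count matrix (genes x cells) with positive margins; dense or
#'   sparse.
#' @param M number of latent factors (0 gives the intercept-only model).
#' @param tau rate of the Exponential prior on singular values
#'   (nuclear-norm penalty); default 0 (unpenalized MLE).
#' @param maxIter maximum outer iterations.
#' @param tol relative-objective convergence tolerance.
#' @param cap linear-predictor overflow cap (natural-log scale).
#' @param centerFactors keep factors orthogonal to the intercept
#'   directions (see \code{\link{workingUpdate}}).
#' @param innerSteps number of applications of the soft-thresholded SVD
#'   update per outer iteration, with the weights and working response
#'   held fixed (the weighted low-rank subproblem is itself solved by
#'   iterating the update); more inner steps progress further per
#'   reweighting at lower cost than full outer iterations.
#' @param seed optional integer; fitting is deterministic, the seed is
#'   recorded for interface uniformity with the stochastic tools.
#' @return a canonical \code{\link{BilinearFit}} with the per-iteration
#'   objective in its trace.
#' @examples
#' sim <- simulateGBM(I = 40, J = 60, M = 2, kappa = 2, seed = 1)
#' fit <- fitGBM(sim$Y, M = 2)
#' singularValues(fit)
#' @export
fitGBM <- function(Y, M, tau = 0, maxIter = 100, tol = 1e-6, cap = 30,
                   centerFactors = TRUE, innerSteps = 5, seed = NULL) {
  innerSteps <- max(1L, as.integer(innerSteps))
  Y <- validateCounts(Y)
  checkMargins(Y)
  if (M > min(dim(Y))) stop("M must be <= min(I, J)")
  fit <- initializeFit(Y, tau = tau)
  # running state: linear predictor, means, penalized objective of `fit`
  X <- matrix(0, nrow(Y), ncol(Y))
  eta <- .capCheck(X + fit@alpha + rep(fit@beta, each = nrow(Y)), cap)
  mu <- exp(eta)
  obj <- sum(Y * eta) - sum(mu)
  trace <- obj
  best <- fit; bestObj <- obj
  converged <- FALSE
  basis <- NULL
  evalCand <- function(cand) {
    Xc <- .interaction(cand)
    etaC <- .capCheck(Xc + cand@alpha + rep(cand@beta, each = nrow(Y)), cap)
    muC <- exp(etaC)
    list(fit = cand, X = Xc, eta = etaC, mu = muC,
      obj = sum(Y * etaC) - sum(muC) - tau * sum(cand@sigma))
  }
  for (it in seq_len(maxIter)) {
    if (M > 0L) {
      ms <- max(mu)
      A <- X + (Y - mu) / ms
      if (innerSteps > 1L) {
        # repeated application of the update with the weights and working
        # response held fixed (W = mu/mu*, W o Z precomputed)
        W <- mu / ms
        WZ <- (mu * X + Y - mu) / ms
      }
      alpha <- fit@alpha; beta <- fit@beta
      for (inner in seq_len(innerSteps)) {
        if (inner == innerSteps && centerFactors) {
          dc <- .doubleCenter(A)
          A <- dc$Ac
          alpha <- alpha + dc$row
          beta <- beta + dc$col
        }
        s <- .truncSVD(A, M, warm = basis)
        basis <- s$basis
        d <- pmax(s$d - tau, 0)
        keep <- d > 0
        if (inner < innerSteps) {
          Xt <- tcrossprod(
            sweep(s$u[, keep, drop = FALSE], 2L, d[keep], `*`),
            s$v[, keep, drop = FALSE])
          A <- WZ + Xt - W * Xt
        }
      }
      cand <- .newFit(alpha, beta, s$u[, keep, drop = FALSE], d[keep],
        s$v[, keep, drop = FALSE], tau = tau, validate = FALSE)
      st <- evalCand(updateIntercepts(Y, cand, cap = cap))
      halvings <- 0L
      while (st$obj < obj - 1e-8 && halvings < 5L) {
        Xmid <- 0.5 * (X + st$X)
        udv <- svdSoftThreshold(Xmid, M, 0)
        cand <- .newFit(st$fit@alpha, st$fit@beta, udv$U, udv$sigma,
          udv$V, tau = tau, validate = FALSE)
        st <- evalCand(updateIntercepts(Y, cand, cap = cap))
        halvings <- halvings + 1L
      }
    } else {
      st <- evalCand(updateIntercepts(Y, fit, cap = cap))
    }
    fit <- st$fit; X <- st$X; mu <- st$mu
    objNew <- st$obj
    trace <- c(trace, objNew)
    if (objNew > bestObj) {
      bestObj <- objNew
      best <- fit
    }
    if (abs(objNew - obj) / (abs(objNew) + 1) < tol) {
      converged <- TRUE
      obj <- objNew
      break
    }
    obj <- objNew
  }
  if (!converged) {
    warning("IRSVD did not converge in ", maxIter,
      " iterations; returning best iterate")
    fit <- best
  }
  out <- canonicalizeFit(fit@alpha, fit@beta, fit@U, fit@sigma, fit@V,
    tau = tau, trace = trace, converged = converged)
  dimnames(out@U) <- list(rownames(Y), NULL)
  dimnames(out@V) <- list(colnames(Y), NULL)
  names(out@alpha) <- rownames(Y)
  names(out@beta) <- colnames(Y)
  out
}
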