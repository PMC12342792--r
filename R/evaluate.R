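# Evaluation metrics (basis-free subspace distance, count splitting,
# out-of-sample log-likelihood, adjusted Rand index) and the
# transformation-plus-PCA baselines.

#' Distance between the column spaces of two score matrices
#'
#' Frobenius norm of the difference of the orthogonal projectors onto the
#' column spaces: \eqn{\|\Pi_{\hat V} - \Pi_V\|_F} with \eqn{\Pi_V =
#' V(V^TV)^{-1}V^T}. Basis-free: invariant to any invertible
#' recombination of the columns. Computed from orthonormal bases without
#' forming the J x J projectors, via
#' \eqn{\|\Pi_1 - \Pi_2\|_F^2 = r_1 + r_2 - 2\|Q_1^T Q_2\|_F^2}.
#'
#' @param Vhat,V matrices with the same number of rows, full column rank.
#' @return non-negative distance (equals \eqn{\sqrt{2M}} for orthogonal
#'   rank-M subspaces).
#' @export
subspaceDistance <- function(Vhat, V) {
  Vhat <- as.matrix(Vhat); V <- as.matrix(V)
  if (nrow(Vhat) != nrow(V)) stop("score matrices must have the same rows")
  q1 <- qr(Vhat); q2 <- qr(V)
  if (q1$rank < ncol(Vhat) || q2$rank < ncol(V))
    stop("rank-deficient score matrix")
  Q1 <- qr.Q(q1); Q2 <- qr.Q(q2)
  d2 <- ncol(Q1) + ncol(Q2) - 2 * sum(crossprod(Q1, Q2)^2)
  sqrt(max(d2, 0))
}

#' Split a count matrix by binomial thinning
#'
#' Entrywise \eqn{Y^{\mathrm{test}}_{ij} \sim \mathrm{Binomial}(Y_{ij},
#' p)} and \eqn{Y^{\mathrm{train}} = Y - Y^{\mathrm{test}}}, so the two
#' halves always sum to \eqn{Y}; when the counts are Poisson the halves
#' are independent (Poisson thinning), giving valid train/test pairs.
#'
#' @param Y count matrix.
#' @param p thinning probability in (0, 1); default 1/2.
#' @param seed optional integer seed.
#' @return list with matrices \code{train} and \code{test}.
#' @export
countSplit <- function(Y, p = 0.5, seed = NULL) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  if (!is.null(seed)) withr::local_seed(seed)
  Ytest <- matrix(rbinom(length(Y), size = as.integer(Y), prob = p),
    nrow(Y), ncol(Y), dimnames = dimnames(Y))
  list(train = Y - Ytest, test = Ytest)
}

#' Out-of-sample Poisson log-likelihood
#'
#' \eqn{\sum_{ij} (Y_{ij} \log \hat\mu_{ij} - \hat\mu_{ij})}, additive
#' constants removed. \code{Y} may be a held-out count matrix or, when the
#' generating truth is known, the true mean matrix (the oracle variant
#' \eqn{\sum_{ij} (\mu_{ij}\log\hat\mu_{ij} - \hat\mu_{ij})}, maximized at
#' \eqn{\hat\mu = \mu}).
#'
#' @param Y held-out counts (or true means), genes x cells.
#' @param muHat matrix of fitted means, all entries > 0.
#' @return a single number.
#' @export
oosLogLik <- function(Y, muHat) {
  if (!all(dim(Y) == dim(muHat))) stop("dimension mismatch")
  if (any(muHat <= 0)) stop("fitted means must be positive")
  sum(Y * log(muHat)) - sum(muHat)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement under the permutation model;
#' 1 for identical partitions up to relabeling, about 0 for independent
#' ones.
#'
#' @param a,b label vectors of equal length.
#' @return the ARI.
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  mclust::adjustedRandIndex(a, b)
}

# PCA scores of a genes x cells matrix: center each gene across cells,
# SVD, return cell coordinates on the leading components
.pcaScores <- function(Z, nPC) {
  Zc <- Z - rowMeans(Z)
  nPC <- min(nPC, nrow(Z), ncol(Z))
  s <- svd(Zc, nu = 0, nv = nPC)
  sweep(s$v, 2L, s$d[seq_len(nPC)], `*`)
}

#' Log-transformation PCA baselines
#'
#' \code{logPCA} computes \eqn{Z_{ij} = \log(L Y_{ij}/S_j + 1)} with
#' library sizes \eqn{S_j} and applies PCA (gene-wise centering). With
#' \code{scale = FALSE} the size factor is \eqn{L =
#' \mathrm{median}(S_1,\ldots,S_J)}; with \code{scale = TRUE}, \eqn{L =
#' 10^4} and rows of Z are additionally standardized to zero mean and unit
#' variance (zero-variance rows dropped with a warning) — the defaults of
#' the two major single-cell toolkits.
#'
#' @param Y count matrix with positive column sums.
#' @param nPC number of score dimensions to return.
#' @param scale row-standardize (and use fixed L = 1e4)?
#' @param L optional explicit size factor overriding the defaults.
#' @return J x nPC matrix of cell scores.
#' @export
logPCA <- function(Y, nPC = 2, scale = FALSE, L = NULL) {
  .pcaScores(.logTransform(Y, scale = scale, L = L), nPC)
}

.logTransform <- function(Y, scale = FALSE, L = NULL) {
  S <- colSums(Y)
  if (any(S == 0)) stop("zero column sums")
  if (is.null(L)) L <- if (scale) 1e4 else median(S)
  Z <- log1p(L * sweep(Y, 2L, S, `/`))
  if (scale) {
    v <- apply(Z, 1L, var)
    if (any(v == 0)) {
      warning(sum(v == 0), " constant gene(s) dropped before scaling")
      Z <- Z[v > 0, , drop = FALSE]
      v <- v[v > 0]
    }
    Z <- (Z - rowMeans(Z)) / sqrt(v)
  }
  Z
}

#' @importFrom stats median var
NULL

#' Analytic Pearson residual PCA baseline
#'
#' Closed-form means \eqn{\hat\mu_{ij} = (\sum_j Y_{ij})(\sum_i
#' Y_{ij})/\sum_{ij} Y_{ij}}, residuals \eqn{Z_{ij} = (Y_{ij} -
#' \hat\mu_{ij})/\sqrt{\hat\mu_{ij} + \hat\mu_{ij}^2/\theta}} with fixed
#' pseudo-dispersion \eqn{\theta} (default 100; \eqn{\theta \to \infty}
#' gives pure Poisson Pearson residuals), then PCA with gene-wise
#' centering.
#'
#' @param Y count matrix with positive margins.
#' @param theta positive dispersion constant.
#' @param nPC number of score dimensions to return.
#' @return J x nPC matrix of cell scores.
#' @export
aprPCA <- function(Y, theta = 100, nPC = 2) {
  tot <- sum(Y)
  if (tot == 0) stop("zero total count")
  mu <- outer(rowSums(Y), colSums(Y)) / tot
  Z <- (Y - mu) / sqrt(mu + mu^2 / theta)
  Z[!is.finite(Z)] <- 0
  .pcaScores(Z, nPC)
}
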