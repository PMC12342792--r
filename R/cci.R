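# Cluster cohesion index: perturb the factor scores by their standard
# errors, recluster with the identical method descriptor, and measure how
# often pairs of cells stay together. Clustering operates on the scaled
# scores V Sigma, so score standard errors are scaled by sigma as well.

#' Perturb factor scores by their standard errors
#'
#' Draws \eqn{\tilde v_{jm} \sim N(\hat v_{jm}, \mathrm{se}(\hat
#' v_{jm})^2)} independently for every entry.
#'
#' @param V J x M score matrix.
#' @param seV J x M matrix of standard errors (>= 0).
#' @param seed optional integer seed.
#' @return J x M matrix of perturbed scores.
#' @export
perturbScores <- function(V, seV, seed = NULL) {
  if (!all(dim(V) == dim(seV))) stop("V and seV must have the same shape")
  if (!is.null(seed)) withr::local_seed(seed)
  V + matrix(rnorm(length(V)), nrow(V), ncol(V)) * seV
}

#' Cluster cells on factor scores
#'
#' Default backend builds a k-nearest-neighbor graph (Euclidean distance,
#' symmetrized) on the score rows and runs Louvain community detection at
#' the given resolution — the default pipeline of the major single-cell
#' toolkits (k = 20, resolution = 0.8). A k-means backend is provided for
#' deterministic tests.
#'
#' @param scores J x M matrix (typically the scaled scores
#'   \code{\link{scaledScores}}).
#' @param method "louvain" or "kmeans".
#' @param k neighbors for the kNN graph (reduced with a warning when
#'   J <= k).
#' @param resolution Louvain resolution parameter.
#' @param centers number of clusters for the k-means backend.
#' @param seed optional integer seed (community detection and k-means are
#'   randomized).
#' @return a \code{\link{CellClustering}}.
#' @export
clusterCells <- function(scores, method = c("louvain", "kmeans"), k = 20,
                         resolution = 0.8, centers = NULL, seed = NULL) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  J <- nrow(scores)
  if (J < 2L) stop("need at least two cells to cluster")
  if (!is.null(seed)) withr::local_seed(seed)
  if (method == "kmeans") {
    if (is.null(centers)) stop("kmeans backend needs 'centers'")
    km <- kmeans(scores, centers = centers, nstart = 10)
    labels <- as.integer(km$cluster)
    K <- length(unique(labels))
  } else {
    if (k >= J) {
      warning("k reduced to ", J - 1L, " (only ", J, " cells)")
      k <- J - 1L
    }
    g <- .knnGraph(scores, k)
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    labels <- as.integer(igraph::membership(comm))
    K <- max(labels)
  }
  new("CellClustering", labels = labels, K = as.integer(K),
    method = method,
    params = list(k = k, resolution = resolution, centers = centers,
      seed = seed))
}

.knnGraph <- function(scores, k) {
  J <- nrow(scores)
  if (requireNamespace("RANN", quietly = TRUE)) {
    nn <- RANN::nn2(scores, k = k + 1L)$nn.idx[, -1L, drop = FALSE]
  } else {
    D <- as.matrix(dist(scores))
    diag(D) <- Inf
    nn <- t(apply(D, 1L, function(d) order(d)[seq_len(k)]))
  }
  edges <- cbind(rep(seq_len(J), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

# re-run the clustering recorded in a CellClustering on new scores
.recluster <- function(base, scores, seed = NULL) {
  clusterCells(scores, method = base@method, k = base@params$k,
    resolution = base@params$resolution, centers = base@params$centers,
    seed = seed)
}

#' Fraction of cell pairs still co-clustered
#'
#' Over all unordered pairs (j in cluster k of the original clustering,
#' j' in cluster k2, j != j'), the fraction assigned the same label in the
#' new clustering. With \code{k == k2} this is the within-cluster cohesion
#' fraction (requires cluster size >= 2).
#'
#' @param orig,new \code{\link{CellClustering}} objects (or integer label
#'   vectors) over the same cells.
#' @param k,k2 cluster indices in the original clustering.
#' @return a fraction in [0, 1].
#' @export
coMembershipFraction <- function(orig, new, k, k2 = k) {
  lo <- if (is(orig, "CellClustering")) orig@labels else as.integer(orig)
  ln <- if (is(new, "CellClustering")) new@labels else as.integer(new)
  if (length(lo) != length(ln)) stop("clusterings must cover the same cells")
  F <- .coMembershipMatrix(lo, ln, K = max(lo))
  val <- F[k, k2]
  if (is.na(val)) {
    if (k == k2) stop("cluster ", k, " has fewer than 2 cells") else
      stop("empty cluster")
  }
  val
}

# K x K matrix of co-membership fractions via the contingency table;
# diagonal NA for singleton clusters
.coMembershipMatrix <- function(labelsOrig, labelsNew, K) {
  Tab <- table(factor(labelsOrig, levels = seq_len(K)), labelsNew)
  n <- rowSums(Tab)
  P <- tcrossprod(Tab)      # ordered co-clustered pairs incl. j = j'
  Fm <- P / outer(n, n)
  diag(Fm) <- ifelse(n >= 2, (diag(P) - n) / (n * (n - 1)), NA_real_)
  Fm[n == 0, ] <- NA_real_
  Fm[, n == 0] <- NA_real_
  unname(as.matrix(Fm))
}

#' Cluster cohesion index with inter-cluster cohesion matrix
#'
#' Repeats \code{nReps} times: perturb the scaled scores by their (scaled)
#' standard errors, recluster with the exact method descriptor of the base
#' clustering (fresh seed each repetition, capturing algorithmic
#' stochasticity), and record the co-membership fractions for every pair
#' of base clusters. The CCI of cluster k is the mean of the within-k
#' fraction; off-diagonal means give the inter-cluster cohesion index.
#' Singleton clusters have no pairs and come back \code{NA}.
#'
#' @param fit a \code{\link{BilinearFit}}.
#' @param se a \code{\link{FactorSE}} for the fit.
#' @param base the \code{\link{CellClustering}} being assessed (computed
#'   on \code{scaledScores(fit)}).
#' @param nReps perturbation repetitions (default 100).
#' @param seed optional integer seed.
#' @return a \code{\link{CCIResult}} (null threshold unset; see
#'   \code{\link{cciNullThreshold}}).
#' @export
computeCCI <- function(fit, se, base, nReps = 100, seed = NULL) {
  if (nReps < 1L) stop("nReps must be >= 1")
  if (!is.null(seed)) withr::local_seed(seed)
  K <- nClusters(base)
  if (K == 1L)
    warning("base clustering has a single cluster; CCI is trivially 1")
  scores <- scaledScores(fit)
  seS <- sweep(scoreSE(se), 2L, singularValues(fit), `*`)
  repSeeds <- sample.int(.Machine$integer.max, nReps)
  acc <- matrix(0, K, K)
  cnt <- matrix(0L, K, K)
  for (r in seq_len(nReps)) {
    Vt <- perturbScores(scores, seS)
    cl <- .recluster(base, Vt, seed = repSeeds[r])
    Fm <- .coMembershipMatrix(base@labels, cl@labels, K)
    ok <- !is.na(Fm)
    acc[ok] <- acc[ok] + Fm[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  Fbar <- ifelse(cnt > 0, acc / cnt, NA_real_)
  new("CCIResult", cci = diag(Fbar), interCCI = Fbar,
    nullThreshold = NA_real_, nReps = as.integer(nReps))
}

#' Null significance threshold for CCIs
#'
#' Computes the CCI values that would have been generated under the null
#' model of no latent structure (V = 0), in which the means reduce to the
#' intercept-only \eqn{\exp(\alpha_i + \beta_j)}.
#'
#' With \code{method = "refit"} (the default) each repetition simulates a
#' full null count matrix from the intercept-only means, refits the
#' bilinear model at the same rank, reclusters its scaled scores with the
#' base method descriptor, and computes per-cluster CCIs from
#' \code{innerReps} perturb-and-recluster draws — the identical pipeline
#' the observed CCIs went through. Because a dataset is judged by whether
#' *any* of its clusters exceeds the threshold, the threshold is the
#' \code{probs} quantile of the per-repetition \emph{maximum} CCI.
#'
#' \code{method = "scores"} is a fast approximation that skips the refit:
#' it draws null score matrices \eqn{\tilde V^{(0)} \sim N(0,
#' \mathrm{se}^2)} at the null-mean standard errors, clusters them,
#' perturbs once more, and pools per-cluster fractions. It understates the
#' cohesion of the spurious structure a real fit extracts from null data
#' (fitted null scores are SVD-optimized, not white), so its threshold is
#' anti-conservative; it is kept for cheap exploratory use.
#'
#' @param fit a \code{\link{BilinearFit}}.
#' @param base a \code{\link{CellClustering}} providing the method
#'   descriptor.
#' @param nReps null repetitions (warning below 5).
#' @param innerReps perturbation draws per refit repetition
#'   (\code{method = "refit"} only).
#' @param probs quantile defining the threshold (default 0.95).
#' @param method "refit" (full pipeline on simulated null data) or
#'   "scores" (score-level approximation).
#' @param maxIter iteration budget for the null refits.
#' @param seed optional integer seed.
#' @param cap linear-predictor cap.
#' @return the threshold (a number in [0, 1]); the per-repetition null
#'   CCIs are in attribute \code{"null_cci"}.
#' @export
cciNullThreshold <- function(fit, base, nReps = 10, innerReps = 4,
                             probs = 0.95, method = c("refit", "scores"),
                             maxIter = 200, seed = NULL, cap = 30) {
  method <- match.arg(method)
  if (nReps < 5L) warning("fewer than 5 null repetitions; threshold noisy")
  if (!is.null(seed)) withr::local_seed(seed)
  M <- nFactors(fit)
  I <- length(fit@alpha); J <- length(fit@beta)
  mu0 <- exp(.capCheck(
    outer(fit@alpha, rep(1, J)) + rep(fit@beta, each = I), cap))
  repSeeds <- sample.int(.Machine$integer.max, 3L * nReps)
  if (method == "scores") {
    se0 <- .blockSE(fit@U, fit@sigma, mu0)
    seS <- sweep(se0, 2L, fit@sigma, `*`)
    pool <- numeric(0)
    for (r in seq_len(nReps)) {
      V0 <- matrix(rnorm(J * M), J, M) * seS
      cl0 <- .recluster(base, V0, seed = repSeeds[2L * r - 1L])
      Vt <- V0 + matrix(rnorm(J * M), J, M) * seS
      cl1 <- .recluster(base, Vt, seed = repSeeds[2L * r])
      Fm <- .coMembershipMatrix(cl0@labels, cl1@labels, nClusters(cl0))
      d <- diag(Fm)
      pool <- c(pool, d[!is.na(d)])
    }
    thr <- unname(quantile(pool, probs = probs, type = 7))
    attr(thr, "null_cci") <- pool
    return(thr)
  }
  maxima <- numeric(nReps)
  pool <- numeric(0)
  for (r in seq_len(nReps)) {
    withr::with_seed(repSeeds[3L * r - 2L], {
      Y0 <- matrix(rpois(I * J, mu0), I, J)
    })
    keepR <- rowSums(Y0) > 0; keepC <- colSums(Y0) > 0
    Y0 <- Y0[keepR, keepC, drop = FALSE]
    fit0 <- suppressWarnings(fitGBM(Y0, M = M, tau = fit@tau,
      maxIter = maxIter, cap = cap))
    se0 <- scoreStandardErrors(fit0)
    base0 <- .recluster(base, scaledScores(fit0),
      seed = repSeeds[3L * r - 1L])
    res0 <- computeCCI(fit0, se0, base0, nReps = innerReps,
      seed = repSeeds[3L * r])
    d <- cci(res0)
    d <- d[!is.na(d)]
    pool <- c(pool, d)
    maxima[r] <- if (length(d)) max(d) else NA_real_
  }
  thr <- unname(quantile(maxima[!is.na(maxima)], probs = probs, type = 7))
  attr(thr, "null_cci") <- pool
  thr
}
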