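# Simulators: the bilinear-model generator with Haar-orthonormal factors,
# the four-cell-type marker-gene benchmark, and homogeneous Poisson noise
# nulls. All are seeded and deterministic given the seed.

#' Sample an orthonormal matrix uniformly (Haar) from the Stiefel manifold
#'
#' QR orthogonalization of a standard Gaussian matrix with the sign fix
#' that makes the diagonal of the triangular factor positive, which yields
#' the unique Haar-invariant distribution on n x M matrices with
#' orthonormal columns.
#'
#' @param n number of rows.
#' @param M number of columns (M <= n).
#' @param seed optional integer seed.
#' @return n x M matrix with orthonormal columns.
#' @export
sampleStiefel <- function(n, M, seed = NULL) {
  if (M > n) stop("M must be <= n")
  if (!is.null(seed)) withr::local_seed(seed)
  G <- matrix(rnorm(n * M), n, M)
  qrG <- qr(G)
  Q <- qr.Q(qrG)
  d <- sign(diag(qr.R(qrG)))
  d[d == 0] <- 1
  sweep(Q, 2L, d, `*`)
}

#' Simulate counts from the Poisson bilinear model
#'
#' Draws loadings and scores uniformly from the Stiefel manifold, sets
#' \eqn{\sigma_m = (\kappa m / M)(\sqrt I + \sqrt J)}, draws the gene and
#' cell intercepts i.i.d. standard normal, and samples
#' \eqn{Y_{ij} \sim \mathrm{Poisson}(\mu_{ij})} independently. The signal
#' strength \eqn{\kappa} of 2 corresponds to low latent variability and 5
#' to high latent variability. The returned truth is in canonical form
#' (singular values re-sorted to non-increasing order; the spanned
#' subspace is unchanged).
#'
#' @param I genes, J cells, M factors.
#' @param kappa positive signal-strength multiplier.
#' @param seed optional integer seed.
#' @param cap linear-predictor overflow cap.
#' @return list with \code{Y} (count matrix) and \code{truth}
#'   (a \code{\link{BilinearFit}} holding the generating parameters).
#' @export
simulateGBM <- function(I, J, M, kappa = 2, seed = NULL, cap = 30) {
  if (M > min(I, J)) stop("M must be <= min(I, J)")
  if (kappa <= 0) stop("kappa must be positive")
  if (!is.null(seed)) withr::local_seed(seed)
  U <- sampleStiefel(I, M)
  V <- sampleStiefel(J, M)
  sigma <- (kappa * seq_len(M) / M) * (sqrt(I) + sqrt(J))
  alpha <- rnorm(I)
  beta <- rnorm(J)
  truth <- canonicalizeFit(alpha, beta, U, sigma, V)
  mu <- meanMatrix(truth, cap = cap)
  Y <- matrix(rpois(I * J, mu), I, J)
  rownames(Y) <- paste0("gene", seq_len(I))
  colnames(Y) <- paste0("cell", seq_len(J))
  names(truth@alpha) <- rownames(Y)
  names(truth@beta) <- colnames(Y)
  list(Y = Y, truth = truth)
}

#' Default configuration of the marker-gene benchmark
#'
#' Four cell types distinguished by two marker genes: gene 1 has moderate
#' mean in type A, low in B, high in C and D; gene 2 is low in A, B and C
#' and high in D. A and B are rare (25 cells each), C and D common (475
#' each), for 1000 cells total; the remaining genes are i.i.d. Poisson
#' noise at the null rate. The default marker depths are deliberately
#' high (illustrative, not typical transcriptome-wide expression): with
#' only 25 cells in each rare type, the gene-1 contrast must carry enough
#' Fisher information to clear the detection floor of a 1000 x 1000 count
#' matrix, and the high common-type mean is exactly the regime where
#' residual-based normalization (fixed pseudo-dispersion 100) shrinks the
#' signal that a likelihood fit retains.
#'
#' @param nCells integer vector of cells per type (A, B, C, D).
#' @param gene1Means,gene2Means positive mean expression of the two marker
#'   genes per type.
#' @param nNullGenes number of pure-noise genes.
#' @param nullRate Poisson rate of the noise genes.
#' @return list of settings consumed by \code{\link{simulateMarkerGenes}}.
#' @export
markerSimConfig <- function(nCells = c(A = 25, B = 25, C = 475, D = 475),
                            gene1Means = c(A = 50, B = 5, C = 150, D = 150),
                            gene2Means = c(A = 1, B = 1, C = 1, D = 120),
                            nNullGenes = 998, nullRate = 1) {
  if (any(gene1Means <= 0) || any(gene2Means <= 0) || nullRate <= 0)
    stop("all means must be positive")
  if (!(gene1Means["B"] < gene1Means["A"] &&
        gene1Means["A"] < gene1Means["C"] &&
        gene1Means["A"] < gene1Means["D"]))
    stop("gene 1 means must satisfy low(B) < moderate(A) < high(C, D)")
  if (!all(gene2Means[c("A", "B", "C")] < gene2Means["D"]))
    stop("gene 2 must be high in D and low elsewhere")
  list(nCells = nCells, gene1Means = gene1Means, gene2Means = gene2Means,
    nNullGenes = nNullGenes, nullRate = nullRate)
}

#' Simulate the two-marker-gene benchmark
#'
#' @param cfg configuration from \code{\link{markerSimConfig}}.
#' @param seed optional integer seed.
#' @return list with \code{Y} (genes x cells counts, markers on the first
#'   two rows) and \code{labels} (factor of cell types).
#' @export
simulateMarkerGenes <- function(cfg = markerSimConfig(), seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  types <- names(cfg$nCells)
  labels <- factor(rep(types, cfg$nCells), levels = types)
  J <- length(labels)
  g1 <- rpois(J, cfg$gene1Means[as.integer(labels)])
  g2 <- rpois(J, cfg$gene2Means[as.integer(labels)])
  noise <- matrix(rpois(cfg$nNullGenes * J, cfg$nullRate),
    cfg$nNullGenes, J)
  Y <- rbind(g1, g2, noise)
  rownames(Y) <- c("marker1", "marker2",
    paste0("null", seq_len(cfg$nNullGenes)))
  colnames(Y) <- paste0("cell", seq_len(J))
  list(Y = Y, labels = labels)
}

#' Simulate homogeneous Poisson noise
#'
#' i.i.d. \eqn{\mathrm{Poisson}(\mathrm{rate})} counts with no structure;
#' the null benchmark on which any clusters found downstream are
#' artifacts of sampling variability.
#'
#' @param I genes, J cells.
#' @param rate positive Poisson rate.
#' @param seed optional integer seed.
#' @return genes x cells count matrix.
#' @export
simulateNullPoisson <- function(I, J, rate = 1, seed = NULL) {
  if (rate <= 0) stop("rate must be positive")
  if (!is.null(seed)) withr::local_seed(seed)
  Y <- matrix(rpois(I * J, rate), I, J)
  rownames(Y) <- paste0("gene", seq_len(I))
  colnames(Y) <- paste0("cell", seq_len(J))
  Y
}

#' Downsample cells stratified by label
#'
#' Utility for constructing class-imbalanced benchmarks: keeps a given
#' fraction of the cells of each label, sampled without replacement.
#'
#' @param Y count matrix, genes x cells.
#' @param labels length-J labels.
#' @param keep named numeric vector of per-label keep fractions in (0, 1].
#' @param seed optional integer seed.
#' @return list with the downsampled \code{Y}, \code{labels}, and kept
#'   column indices \code{idx}.
#' @export
downsampleByLabel <- function(Y, labels, keep, seed = NULL) {
  if (length(labels) != ncol(Y)) stop("labels must have one entry per cell")
  if (!is.null(seed)) withr::local_seed(seed)
  labels <- as.factor(labels)
  idx <- unlist(lapply(levels(labels), function(l) {
    cells <- which(labels == l)
    f <- if (l %in% names(keep)) keep[[l]] else 1
    if (f <= 0 || f > 1) stop("keep fractions must be in (0, 1]")
    sort(sample(cells, max(1L, round(f * length(cells)))))
  }), use.names = FALSE)
  idx <- sort(idx)
  list(Y = Y[, idx, drop = FALSE], labels = labels[idx], idx = idx)
}
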