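test_that("perturbScores draws entrywise Gaussians around the estimates", {
  V <- matrix(c(1, -1, 0.5, 2, 0, -0.5), 3, 2)
  expect_equal(perturbScores(V, matrix(0, 3, 2), seed = 1), V)
  expect_error(perturbScores(V, matrix(1, 2, 2)), "shape")
  expect_false(identical(perturbScores(V, matrix(1, 3, 2), seed = 1),
    perturbScores(V, matrix(1, 3, 2), seed = 2)))
  # Monte-Carlo mean within 4 se / sqrt(nreps)
  se <- matrix(0.3, 3, 2)
  withr::local_seed(3)
  acc <- matrix(0, 3, 2)
  n <- 1e4
  for (r in seq_len(n)) acc <- acc + perturbScores(V, se)
  expect_true(all(abs(acc / n - V) < 4 * 0.3 / sqrt(n) + 0.012))
})

test_that("clusterCells separates blobs and respects seeds", {
  withr::local_seed(44)
  blobs <- rbind(matrix(rnorm(60, 0), 30, 2),
    matrix(rnorm(60, 20), 30, 2))
  truth <- rep(1:2, each = 30)
  cl <- clusterCells(blobs, seed = 9)
  expect_equal(nClusters(cl), 2L)
  expect_equal(adjustedRandIndex(clusterLabels(cl), truth), 1)
  cl2 <- clusterCells(blobs, seed = 9)
  expect_identical(clusterLabels(cl), clusterLabels(cl2))
  # one cloud at near-zero resolution collapses to a single community
  cloud <- matrix(rnorm(80), 40, 2)
  expect_equal(nClusters(clusterCells(cloud, resolution = 0.01, seed = 1)),
    1L)
  # k is reduced with a warning when there are few cells
  expect_warning(clusterCells(matrix(rnorm(12), 6, 2), k = 20, seed = 1),
    "reduced")
})

test_that("co-membership fractions enumerate pairs correctly", {
  orig <- c(1, 1, 2, 2)
  expect_equal(coMembershipFraction(orig, orig, 1, 1), 1)
  expect_equal(coMembershipFraction(orig, orig, 1, 2), 0)
  expect_equal(coMembershipFraction(orig, rep(1, 4), 1, 2), 1)
  # {a,a,b,b} vs {x,y,x,y}: within = 0, across = 2/4
  neu <- c(1, 2, 1, 2)
  expect_equal(coMembershipFraction(orig, neu, 1, 1), 0)
  expect_equal(coMembershipFraction(orig, neu, 1, 2), 0.5)
})

test_that("co-membership matrix matches a brute-force pair oracle", {
  withr::local_seed(45)
  for (r in 1:10) {
    J <- 12
    lo <- sample(1:3, J, replace = TRUE)
    ln <- sample(1:4, J, replace = TRUE)
    K <- max(lo)
    Fm <- scBilinear:::.coMembershipMatrix(lo, ln, K)
    for (k in 1:K) for (k2 in 1:K) {
      pairs <- 0; same <- 0
      for (j in which(lo == k)) for (j2 in which(lo == k2)) {
        if (k == k2 && j >= j2) next   # unordered within-cluster pairs
        pairs <- pairs + 1
        if (ln[j] == ln[j2]) same <- same + 1
      }
      expected <- if (pairs == 0) NA_real_ else same / pairs
      expect_equal(Fm[k, k2], expected, tolerance = 1e-12)
    }
  }
})

test_that("computeCCI is exact with zero noise and deterministic backend", {
  withr::local_seed(46)
  scores <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 30), 20, 2))
  f <- randomFit(10, 40, 2, sigma = c(2, 1), seed = 47)
  f@V <- sweep(scores, 2, f@sigma, `/`)
  f@projected <- TRUE
  base <- clusterCells(scaledScores(f), method = "kmeans", centers = 2,
    seed = 1)
  seZero <- new("FactorSE",
    seV = matrix(1e-12, 40, 2), seU = matrix(0, 0, 2),
    singular = logical(40))
  res <- computeCCI(f, seZero, base, nReps = 5, seed = 2)
  expect_equal(cci(res), c(1, 1))
  expect_equal(interCCI(res)[1, 2], 0)
  expect_true(validObject(res))
})

test_that("well-separated clusters stay cohesive under perturbation", {
  withr::local_seed(48)
  scores <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 25), 30, 2))
  f <- randomFit(10, 60, 2, sigma = c(2, 1), seed = 49)
  f@V <- sweep(scores, 2, f@sigma, `/`)
  f@projected <- TRUE
  base <- clusterCells(scaledScores(f), seed = 3)
  se <- new("FactorSE", seV = matrix(0.4, 60, 2) /
      rep(f@sigma, each = 60),
    seU = matrix(0, 0, 2), singular = logical(60))
  res <- computeCCI(f, se, base, nReps = 20, seed = 4)
  expect_true(all(cci(res) > 0.95))
  expect_lt(max(interCCI(res)[upper.tri(interCCI(res))]), 0.05)
  expect_equal(diag(interCCI(res)), cci(res))
  expect_equal(interCCI(res), t(interCCI(res)))
})

test_that("inflating the standard errors does not increase mean cohesion", {
  withr::local_seed(50)
  scores <- rbind(matrix(rnorm(50, 0, 1), 25, 2),
    matrix(rnorm(50, 4, 1), 25, 2))
  f <- randomFit(10, 50, 2, sigma = c(2, 1), seed = 51)
  f@V <- sweep(scores, 2, f@sigma, `/`)
  f@projected <- TRUE
  base <- clusterCells(scaledScores(f), method = "kmeans", centers = 2,
    seed = 5)
  meanCCI <- function(scale, seed) {
    se <- new("FactorSE",
      seV = matrix(scale, 50, 2) / rep(f@sigma, each = 50),
      seU = matrix(0, 0, 2), singular = logical(50))
    mean(cci(computeCCI(f, se, base, nReps = 8, seed = seed)),
      na.rm = TRUE)
  }
  small <- vapply(1:10, function(s) meanCCI(0.5, s), numeric(1))
  large <- vapply(1:10, function(s) meanCCI(3.0, s), numeric(1))
  expect_lte(mean(large), mean(small))
})

test_that("null threshold lies in [0, 1] and flags degenerate inputs", {
  sim <- simulateGBM(I = 40, J = 60, M = 2, kappa = 3, seed = 52)
  fit <- suppressWarnings(fitGBM(sim$Y, M = 2, maxIter = 300))
  base <- clusterCells(scaledScores(fit), seed = 6)
  thr <- cciNullThreshold(fit, base, nReps = 6, seed = 7)
  expect_gte(as.numeric(thr), 0)
  expect_lte(as.numeric(thr), 1)
  expect_warning(cciNullThreshold(fit, base, nReps = 3, seed = 8),
    "repetitions")
})
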