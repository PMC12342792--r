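test_that("subspaceDistance is basis-free and matches the dense oracle", {
  withr::local_seed(81)
  V <- matrix(rnorm(40 * 3), 40, 3)
  R <- matrix(rnorm(9), 3, 3)  # invertible with probability 1
  expect_equal(subspaceDistance(V %*% R, V), 0, tolerance = 1e-8)
  e1 <- matrix(c(1, 0, 0), 3, 1); e2 <- matrix(c(0, 1, 0), 3, 1)
  expect_equal(subspaceDistance(e1, e2), sqrt(2), tolerance = 1e-12)
  for (r in 1:5) {
    J <- 30
    A <- matrix(rnorm(J * 2), J, 2); B <- matrix(rnorm(J * 3), J, 3)
    proj <- function(X) X %*% solve(crossprod(X), t(X))
    expect_equal(subspaceDistance(A, B),
      norm(proj(A) - proj(B), "F"), tolerance = 1e-10)
  }
  expect_error(subspaceDistance(matrix(1, 4, 2), matrix(rnorm(8), 4, 2)),
    "rank")
})

test_that("subspaceDistance behaves like a metric on subspaces", {
  withr::local_seed(82)
  J <- 25
  A <- matrix(rnorm(J * 2), J, 2)
  B <- matrix(rnorm(J * 2), J, 2)
  C <- matrix(rnorm(J * 2), J, 2)
  expect_equal(subspaceDistance(A, B), subspaceDistance(B, A),
    tolerance = 1e-12)
  expect_lte(subspaceDistance(A, C),
    subspaceDistance(A, B) + subspaceDistance(B, C) + 1e-12)
})

test_that("countSplit thins exactly and the halves decorrelate", {
  Y <- randomCounts(20, 30, seed = 83)
  sp <- countSplit(Y, seed = 84)
  expect_identical(sp$train + sp$test, Y)
  expect_true(all(sp$test >= 0) && all(sp$train >= 0))
  z <- matrix(0L, 3, 3)
  zsp <- countSplit(z, seed = 85)
  expect_true(all(zsp$train == 0) && all(zsp$test == 0))
  # Poisson thinning: the two halves are uncorrelated
  withr::local_seed(86)
  Yp <- matrix(rpois(1e4, 5), 100, 100)
  sp2 <- countSplit(Yp, seed = 87)
  expect_lt(abs(cor(as.vector(sp2$train), as.vector(sp2$test))),
    4 / sqrt(1e4))
  expect_error(countSplit(Y, p = 1.2), "p must")
})

test_that("count-split halves are exchangeable", {
  Y <- randomCounts(15, 15, seed = 88)
  trainMeans <- testMeans <- numeric(100)
  for (s in 1:100) {
    sp <- countSplit(Y, seed = s)
    trainMeans[s] <- mean(sp$train)
    testMeans[s] <- mean(sp$test)
  }
  expect_lt(abs(mean(trainMeans) - mean(testMeans)),
    3 * sd(trainMeans - testMeans) / sqrt(100))
})

test_that("out-of-sample log-likelihood matches its definition", {
  Y <- matrix(c(2, 0, 1, 3), 2, 2)
  expect_equal(oosLogLik(matrix(0, 2, 2), matrix(1, 2, 2)), -4)
  expect_equal(oosLogLik(Y, matrix(1, 2, 2)), -4)
  mu <- matrix(c(1, 2, 3, 4), 2, 2)
  # the oracle variant is maximized at muHat = mu
  best <- oosLogLik(mu, mu)
  withr::local_seed(89)
  for (r in 1:20)
    expect_lte(oosLogLik(mu, mu * exp(matrix(rnorm(4, 0, 0.2), 2, 2))),
      best)
  expect_error(oosLogLik(Y, matrix(c(1, -1, 1, 1), 2, 2)), "positive")
})

test_that("adjusted Rand index matches the pair-counting oracle", {
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjustedRandIndex(a, c(3, 3, 1, 1, 2, 2)), 1)
  withr::local_seed(90)
  for (r in 1:30) {
    x <- sample(1:3, 6, replace = TRUE)
    y <- sample(1:4, 6, replace = TRUE)
    expect_equal(adjustedRandIndex(x, y), ariOracle(x, y),
      tolerance = 1e-12)
  }
  expect_error(adjustedRandIndex(1:3, 1:4), "length")
})

test_that("log transform matches the size-factor formula", {
  # single cell with counts (1, 3): S = 4, L = median(S) = 4
  Y <- matrix(c(1, 3), 2, 1)
  Z <- scBilinear:::.logTransform(Y)
  expect_equal(as.vector(Z), c(log(2), log(4)))
  # scaled variant drops rows that are constant after the transform
  zeroRow <- rbind(c(0, 0, 0), c(1, 4, 2), c(3, 1, 6))
  expect_warning(Zs <- scBilinear:::.logTransform(zeroRow, scale = TRUE),
    "constant")
  expect_equal(nrow(Zs), 2L)
})

test_that("analytic Pearson residuals behave as specified", {
  # perfectly additive table: residuals vanish, scores are zero
  ones <- matrix(1, 2, 2)
  mu <- outer(rowSums(ones), colSums(ones)) / sum(ones)
  expect_equal(mu, ones)
  sc <- aprPCA(ones, nPC = 1)
  expect_equal(as.vector(sc), c(0, 0), tolerance = 1e-12)
  # theta -> Inf recovers pure Poisson Pearson residuals
  Y <- randomCounts(6, 8, seed = 91)
  muY <- outer(rowSums(Y), colSums(Y)) / sum(Y)
  Zinf <- (Y - muY) / sqrt(muY)
  Zbig <- (Y - muY) / sqrt(muY + muY^2 / 1e12)
  expect_equal(Zbig, Zinf, tolerance = 1e-10)
  # residuals have near-zero gene means on intercept-only data
  withr::local_seed(92)
  mu0 <- exp(outer(rnorm(50, 0, 0.3), rnorm(80, 0, 0.3), "+"))
  Y0 <- matrix(rpois(4000, mu0), 50, 80)
  m0 <- outer(rowSums(Y0), colSums(Y0)) / sum(Y0)
  Z0 <- (Y0 - m0) / sqrt(m0 + m0^2 / 100)
  expect_lt(max(abs(rowMeans(Z0))), 0.5)
})
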