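test_that("meanMatrix evaluates the log-bilinear mean", {
  # intercepts only (sigma -> 0 limit handled as M = 0)
  f <- canonicalizeFit(log(2), log(3), matrix(1, 1, 0), numeric(0),
    matrix(1, 1, 0))
  expect_equal(meanMatrix(f), matrix(6, 1, 1))

  # all-zero linear predictor
  f0 <- randomFit(4, 5, 2, seed = 3)
  f0@alpha[] <- 0; f0@beta[] <- 0; f0@sigma[] <- c(1e-12, 5e-13)
  expect_equal(meanMatrix(f0), matrix(1, 4, 5), tolerance = 1e-10)

  # rank-1 unit-vector case: mu = [[e, 1], [1, 1]]
  f1 <- canonicalizeFit(c(0, 0), c(0, 0), matrix(c(1, 0), 2, 1), 1,
    matrix(c(1, 0), 2, 1))
  expect_equal(meanMatrix(f1), matrix(c(exp(1), 1, 1, 1), 2, 2),
    tolerance = 1e-12)
})

test_that("meanMatrix errors on linear-predictor overflow, naming indices", {
  f <- canonicalizeFit(c(0, 35), c(0, 0), matrix(1, 2, 0), numeric(0),
    matrix(1, 2, 0))
  expect_error(meanMatrix(f), "gene 2")
  expect_silent(meanMatrix(f, cap = 40))
})

test_that("log-likelihood with constants removed matches hand values", {
  I <- 3; J <- 4
  unitFit <- canonicalizeFit(rep(0, I), rep(0, J), matrix(1, I, 0),
    numeric(0), matrix(1, J, 0))
  expect_equal(logLikGBM(matrix(0, I, J), unitFit), -I * J)
  expect_equal(logLikGBM(matrix(1, I, J), unitFit), -I * J)

  unit2 <- canonicalizeFit(c(0, 0), c(0, 0), matrix(1, 2, 0), numeric(0),
    matrix(1, 2, 0))
  expect_equal(logLikGBM(matrix(c(1, 0, 0, 2), 2, 2), unit2), -4)
  expect_error(logLikGBM(matrix(0, 3, 2), unit2), "dimensions")
})

test_that("log-posterior subtracts the nuclear-norm penalty", {
  Y <- randomCounts(4, 5, seed = 2)
  f <- randomFit(4, 5, 2, sigma = c(2, 1), seed = 2)
  expect_equal(logPosteriorGBM(Y, f), logLikGBM(Y, f))  # tau = 0
  f@tau <- 1
  expect_equal(logPosteriorGBM(Y, f), logLikGBM(Y, f) - 3)
  f2 <- f; f2@sigma <- c(2.5, 1)
  expect_equal(
    (logPosteriorGBM(Y, f2) - logLikGBM(Y, f2)) -
      (logPosteriorGBM(Y, f) - logLikGBM(Y, f)),
    -0.5)
})

test_that("canonicalizeFit preserves the mean matrix and enforces the form", {
  withr::local_seed(11)
  for (r in 1:10) {
    I <- sample(3:7, 1); J <- sample(3:7, 1); M <- sample(1:2, 1)
    alpha <- rnorm(I); beta <- rnorm(J)
    U_raw <- matrix(rnorm(I * M), I, M)   # deliberately non-orthogonal
    V_raw <- matrix(rnorm(J * M), J, M)
    sig <- sort(runif(M, 0.5, 2), decreasing = TRUE)
    muRaw <- exp(outer(alpha, beta, "+") +
      tcrossprod(sweep(U_raw, 2, sig, `*`), V_raw))
    f <- canonicalizeFit(alpha, beta, U_raw, sig, V_raw)
    expect_equal(meanMatrix(f, cap = 100), muRaw, tolerance = 1e-10)
    expect_equal(crossprod(f@U), diag(nFactors(f)), tolerance = 1e-8)
    expect_equal(crossprod(f@V), diag(nFactors(f)), tolerance = 1e-8)
    expect_false(is.unsorted(rev(f@sigma)))
    # sign convention: largest-|entry| of each U column positive
    for (m in seq_len(nFactors(f)))
      expect_gt(f@U[which.max(abs(f@U[, m])), m], 0)
  }
})

test_that("canonicalizeFit is idempotent and handles sign symmetry", {
  f <- randomFit(5, 6, 2, seed = 4)
  g <- canonicalizeFit(f@alpha, f@beta, f@U, f@sigma, f@V)
  expect_equal(g@U, f@U, tolerance = 1e-10)
  expect_equal(g@sigma, f@sigma, tolerance = 1e-10)
  # a joint sign flip of matching U and V columns leaves mu unchanged and
  # the canonical form restores the sign convention on both
  h <- canonicalizeFit(f@alpha, f@beta,
    sweep(f@U, 2, c(-1, 1), `*`), f@sigma,
    sweep(f@V, 2, c(-1, 1), `*`))
  expect_equal(meanMatrix(h), meanMatrix(f), tolerance = 1e-10)
  expect_equal(h@U, f@U, tolerance = 1e-10)
  expect_equal(h@V, f@V, tolerance = 1e-10)
  # zero singular values are dropped with a warning
  expect_warning(
    z <- canonicalizeFit(f@alpha, f@beta, f@U, c(2, 0), f@V),
    "dropped")
  expect_equal(nFactors(z), 1L)
})

test_that("Poisson log-likelihood is maximized at mu = Y", {
  Y <- matrix(c(1, 3, 2, 4), 2, 2)
  llAt <- function(mu) sum(Y * log(mu) - mu)
  best <- llAt(Y)
  withr::local_seed(5)
  for (r in 1:50) {
    expect_lte(llAt(Y * exp(matrix(rnorm(4, 0, 0.3), 2, 2))), best)
  }
})

test_that("M = 0 model matches the generic Poisson two-way GLM", {
  Y <- matrix(c(5, 1, 2, 3, 4, 2, 0, 7, 1, 2, 3, 1), 3, 4)
  rownames(Y) <- paste0("g", 1:3); colnames(Y) <- paste0("c", 1:4)
  fit0 <- fitGBM(Y, M = 0)
  df <- data.frame(y = as.vector(Y),
    gene = factor(rep(1:3, 4)), cell = factor(rep(1:4, each = 3)))
  g <- glm(y ~ gene + cell, family = poisson(), data = df)
  expect_equal(as.vector(meanMatrix(fit0)), unname(fitted(g)),
    tolerance = 1e-8)
})

test_that("zero margins are rejected and the filter drops them", {
  Y <- randomCounts(4, 5, seed = 9)
  Y[2, ] <- 0
  expect_error(fitGBM(Y, M = 1), "all-zero")
  expect_message(Yf <- filterZeroMargins(Y), "removed")
  expect_equal(nrow(Yf), 3L)
  expect_error(validateCounts(matrix(c(1, -1, 2, 3), 2, 2)),
    "non-negative")
  expect_error(validateCounts(matrix(c(1, 0.5, 2, 3), 2, 2)),
    "non-negative integers")
})
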