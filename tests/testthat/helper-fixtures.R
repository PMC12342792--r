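# Shared fixtures: everything is generated in code at test time.

# random count matrix with positive margins
randomCounts <- function(I, J, lambda = 3, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  repeat {
    Y <- matrix(rpois(I * J, lambda), I, J)
    if (all(rowSums(Y) > 0) && all(colSums(Y) > 0)) break
  }
  rownames(Y) <- paste0("g", seq_len(I))
  colnames(Y) <- paste0("c", seq_len(J))
  Y
}

# a small canonical fit with given dimensions (deterministic given seed)
randomFit <- function(I, J, M, sigma = NULL, seed = 1, centered = FALSE) {
  withr::local_seed(seed)
  U <- sampleStiefel(I, M)
  V <- sampleStiefel(J, M)
  if (centered) {
    U <- qr.Q(qr(sweep(U, 2L, colMeans(U))))
    V <- qr.Q(qr(sweep(V, 2L, colMeans(V))))
  }
  if (is.null(sigma)) sigma <- sort(runif(M, 1, 3), decreasing = TRUE)
  canonicalizeFit(rnorm(I, 0, 0.5), rnorm(J, 0, 0.5), U, sigma, V)
}

# match fitted factor columns to reference columns by absolute correlation
# and flip signs accordingly
alignFactors <- function(Vhat, Vref, se = NULL) {
  co <- cor(Vhat, Vref)
  perm <- apply(abs(co), 2L, which.max)
  sgn <- sign(co[cbind(perm, seq_len(ncol(Vref)))])
  out <- sweep(Vhat[, perm, drop = FALSE], 2L, sgn, `*`)
  if (is.null(se)) return(out)
  list(V = out, se = se[, perm, drop = FALSE])
}

# brute-force pair-counting adjusted Rand index
ariOracle <- function(a, b) {
  n <- length(a)
  sameA <- outer(a, a, "==")[upper.tri(diag(n))]
  sameB <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(sameA & sameB)
  n10 <- sum(sameA & !sameB)
  n01 <- sum(!sameA & sameB)
  n00 <- sum(!sameA & !sameB)
  denom <- ((n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00))
  if (denom == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / denom
}
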