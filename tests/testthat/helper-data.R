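# Small fixtures built in code, shared across test files.

# Well-conditioned synthetic dataset used by several module tests.
smallData <- function(n = 150, m = 60, k = 2, seed = 7, ...) {
  generateDataset(n = n, m = m, k = k, seed = seed, ...)
}

# Convergence-grade fit: gradient norm driven to `tol`.
convergedFit <- function(data, tol = 1e-10, sigmoidMode = "exact",
                         lut = NULL) {
  fitLogisticGD(data, fitConfig(iters = 200000L, tol = tol,
                                sigmoidMode = sigmoidMode), lut)
}

# Triple-loop brute-force X' W M, the independent oracle for the
# crossprod-based implementations.
bruteCross <- function(X, w, M) {
  out <- matrix(0, ncol(X), ncol(M))
  for (a in seq_len(ncol(X)))
    for (b in seq_len(ncol(M)))
      for (i in seq_len(nrow(X)))
        out[a, b] <- out[a, b] + X[i, a] * w[i] * M[i, b]
  out
}

# A deliberately near-balanced Gram matrix with ||4G - I|| < 1.
shrunkGram <- function(k1 = 4, seed = 5, spread = 0.05) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(k1 * k1), k1)))
  ev <- 0.25 + runif(k1, -spread, spread)
  Q %*% diag(ev) %*% t(Q)
}
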