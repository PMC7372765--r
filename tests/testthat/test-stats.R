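test_that("weighted Gram matrix matches closed forms and brute force", {
  X1 <- matrix(1, 4, 1)
  expect_equal(computeGram(X1, rep(0.25, 4)), matrix(1))
  set.seed(1)
  X <- cbind(1, matrix(rnorm(10), 5, 2))
  expect_equal(computeGram(X, rep(1, 5)), crossprod(X))
  w <- runif(5)
  expect_equal(computeGram(X, w), bruteCross(X, w, X), tolerance = 1e-12)
  expect_error(computeGram(X, w[-1]), "length")
  expect_error(computeGram(X, -w), "nonnegative")
})

test_that("weighted cross-product A = X' W S matches brute force", {
  set.seed(2)
  X <- cbind(1, matrix(rnorm(12), 6, 2))
  S <- matrix(rbinom(24, 1, 0.4), 6, 4)
  w <- runif(6)
  expect_equal(computeA(X, w, matrix(0, 6, 4)), matrix(0, 3, 4))
  expect_equal(computeA(X, w, S), bruteCross(X, w, S), tolerance = 1e-12)
  # intercept-only design, constant weights: A_1j = w * colsum(S_j)
  expect_equal(drop(computeA(matrix(1, 6, 1), rep(0.2, 6), S)),
               0.2 * colSums(S))
})

test_that("Taylor inversion returns 4I at order zero and converges", {
  expect_equal(invertGTaylor(diag(3) / 4, order = 0), 4 * diag(3))
  expect_equal(invertGTaylor(diag(3) / 4, order = 7), 4 * diag(3))
  G <- shrunkGram(4, seed = 5)
  expect_equal(invertGTaylor(G, 0), 4 * diag(4))
  exact <- solve(G)
  errs <- vapply(0:8, function(o)
    max(abs(invertGTaylor(G, o) - exact)), numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[9], 1e-5)
  # divergent series warns instead of failing
  expect_warning(invertGTaylor(diag(3), order = 2), "divergent")
})

test_that("Cholesky inversion is exact and rejects indefinite input", {
  expect_equal(invertGExact(diag(3)), diag(3))
  expect_equal(invertGExact(matrix(c(2, 1, 1, 2), 2)),
               matrix(c(2, -1, -1, 2), 2) / 3)
  set.seed(3)
  B <- matrix(rnorm(25), 5)
  G <- crossprod(B) + diag(5)
  expect_lt(max(abs(G %*% invertGExact(G) - diag(5))), 1e-10)
  expect_error(invertGExact(matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("score numerator is the residual-genotype inner product", {
  y <- c(1, 0); p <- c(0.5, 0.5)
  expect_equal(unname(statNumerator(y, p, matrix(c(1, 0), 2, 1))), 0.5)
  expect_equal(unname(statNumerator(y, p, matrix(c(1, 1), 2, 1))), 0)
  set.seed(4)
  S <- matrix(rbinom(30, 1, 0.3), 10, 3)
  p <- runif(10, 0.2, 0.8)
  expect_equal(statNumerator(p, p, S), drop(crossprod(S, rep(0, 10))))
  expect_error(statNumerator(y, p, S), "samples")
})

test_that("score denominator matches the projection closed form", {
  n <- 12
  set.seed(5)
  S <- matrix(rbinom(n * 5, 1, 0.4), n, 5)
  X1 <- matrix(1, n, 1)
  w <- rep(0.21, n)
  A <- computeA(X1, w, S)
  G <- computeGram(X1, w)
  den <- statDenominator(w, S, A, invertGExact(G), exactGinv = TRUE)
  cs <- colSums(S)
  expect_equal(unname(den), 0.21 * cs * (1 - cs / n), tolerance = 1e-12)
  # all-zero SNP column has zero denominator
  S0 <- cbind(S, 0)
  A0 <- computeA(X1, w, S0)
  expect_equal(unname(statDenominator(w, S0, A0, invertGExact(G))[6]), 0)
  # bounded above by the weighted column sums
  expect_true(all(den <= drop(crossprod(S, w)) + 1e-12))
})

test_that("dosage genotypes square explicitly instead of using S*S = S", {
  set.seed(6)
  n <- 20
  X <- cbind(1, rnorm(n))
  Sdos <- matrix(rbinom(n * 4, 2, 0.3), n, 4)
  w <- runif(n, 0.1, 0.25)
  A <- computeA(X, w, Sdos)
  Ginv <- invertGExact(computeGram(X, w))
  den <- statDenominator(w, Sdos, A, Ginv, binaryS = FALSE)
  ref <- drop(crossprod(Sdos^2, w)) - colSums(A * (Ginv %*% A))
  expect_equal(den, ref)
  # the binary shortcut would be wrong here
  expect_false(isTRUE(all.equal(
    den, statDenominator(w, Sdos, A, Ginv, binaryS = TRUE))))
})

test_that("t statistics flag degenerate denominators instead of zeroing", {
  expect_equal(computeTstat(c(0, 1), c(1, 4))$tstat, c(0, 0.5))
  res <- computeTstat(c(1, 1), c(1, 0), nSamplesHint = 100)
  expect_true(is.nan(res$tstat[2]))
  expect_identical(res$masked, c(FALSE, TRUE))
  expect_error(computeTstat(1, -1), "negative denominator")
})

test_that("p-values are two-sided normal and monotone in |t|", {
  expect_identical(tstatToPvalue(0), 1)
  expect_equal(tstatToPvalue(1.959964), 0.05, tolerance = 1e-5)
  t <- seq(0, 6, by = 0.25)
  expect_true(all(diff(tstatToPvalue(t)) < 0))
  expect_equal(tstatToPvalue(-2), tstatToPvalue(2))
})

test_that("projection oracle has valid projector geometry", {
  d <- smallData(n = 100, m = 30, k = 2, seed = 21)
  fit <- convergedFit(d)
  o <- oracleSemiparallel(d, coef(fit))
  P <- o$projector
  expect_lt(max(abs(P %*% P - P)), 1e-10)
  expect_lt(max(abs(P - t(P))), 1e-10)
  # z'* lies in the orthogonal complement of the weighted design span
  p <- predictProbabilities(covariateMatrix(d), coef(fit))
  Xp <- covariateMatrix(d) * sqrt(computeWeights(p))
  expect_lt(max(abs(crossprod(Xp, o$zstarPrime))), 1e-8)
})

test_that("simplified statistic agrees with the oracle at convergence", {
  d <- smallData(n = 150, m = 80, k = 2, seed = 22)
  fit <- convergedFit(d, tol = 1e-10)
  X <- covariateMatrix(d); y <- phenotype(d); S <- genotypeMatrix(d)
  p <- predictProbabilities(X, coef(fit))
  w <- computeWeights(p)
  A <- computeA(X, w, S)
  Ginv <- invertGExact(computeGram(X, w))
  num <- statNumerator(y, p, S)
  den <- statDenominator(w, S, A, Ginv, exactGinv = TRUE)
  o <- oracleSemiparallel(d, coef(fit))
  relNum <- max(abs(num - o$numerator)) / max(abs(o$numerator))
  relDen <- max(abs(den - o$denominator)) / max(abs(o$denominator))
  expect_lt(relNum, 1e-6)
  expect_lt(relDen, 1e-8)
})

test_that("numerator discrepancy shrinks as convergence tightens", {
  d <- smallData(n = 150, m = 80, k = 2, seed = 23)
  disc <- vapply(c(1e-2, 1e-4, 1e-6, 1e-10), function(tol) {
    fit <- convergedFit(d, tol = tol)
    p <- predictProbabilities(covariateMatrix(d), coef(fit))
    num <- statNumerator(phenotype(d), p, genotypeMatrix(d))
    o <- oracleSemiparallel(d, coef(fit))
    max(abs(num - o$numerator))
  }, numeric(1))
  expect_true(all(diff(disc) < 0))
})

test_that("statistics are invariant to a change of design basis", {
  d <- smallData(n = 150, m = 40, k = 2, seed = 24)
  res1 <- snpAssociation(d, fitConfig(iters = 2e5, tol = 1e-11))
  set.seed(9)
  M <- diag(3) + matrix(rnorm(9, sd = 0.15), 3)
  X <- covariateMatrix(d); y <- phenotype(d); S <- genotypeMatrix(d)
  XM <- X %*% M
  f2 <- fitLogisticGD(list(X = XM, y = y), fitConfig(iters = 2e5, tol = 1e-11))
  p2 <- predictProbabilities(XM, coef(f2))
  w2 <- computeWeights(p2)
  A2 <- computeA(XM, w2, S)
  den2 <- statDenominator(w2, S, A2, invertGExact(computeGram(XM, w2)),
                          exactGinv = TRUE)
  num2 <- statNumerator(y, p2, S)
  expect_equal(unname(res1@numerator), unname(num2), tolerance = 1e-8)
  expect_equal(unname(res1@denominator), unname(den2), tolerance = 1e-8)
})

test_that("orthonormalized design makes the Taylor inverse usable", {
  d <- smallData(n = 200, m = 30, k = 3, seed = 27)
  X <- covariateMatrix(d); y <- phenotype(d); S <- genotypeMatrix(d)
  Q <- orthonormalizeDesign(X)
  expect_equal(crossprod(Q), diag(ncol(X)))
  f <- fitLogisticGD(list(X = Q, y = y), fitConfig(iters = 2e5, tol = 1e-11))
  p <- predictProbabilities(Q, coef(f))
  w <- computeWeights(p)
  G <- computeGram(Q, w)
  # near I/4: the series converges and improves on the raw-basis case
  eps <- 4 * G - diag(ncol(G))
  expect_lt(max(abs(eigen(eps, symmetric = TRUE)$values)), 1)
  exact <- invertGExact(G)
  expect_lt(max(abs(invertGTaylor(G, 6) - exact)),
            max(abs(invertGTaylor(G, 1) - exact)))
  # statistics in the orthonormal basis equal the raw-basis statistics
  raw <- snpAssociation(d, fitConfig(iters = 2e5, tol = 1e-11))
  A <- computeA(Q, w, S)
  num <- statNumerator(y, p, S)
  den <- statDenominator(w, S, A, exact, exactGinv = TRUE)
  expect_equal(unname(raw@numerator), unname(num), tolerance = 1e-8)
  expect_equal(unname(raw@denominator), unname(den), tolerance = 1e-8)
})

test_that("end-to-end scan approximates per-SNP Wald refits", {
  d <- smallData(n = 250, m = 60, k = 2, seed = 25)
  res <- snpAssociation(d, fitConfig(iters = 2e5, tol = 1e-10))
  X <- covariateMatrix(d); y <- phenotype(d); S <- genotypeMatrix(d)
  ok <- !res@masked
  wald <- vapply(which(ok), function(j) {
    fitj <- glm(y ~ X - 1 + S[, j], family = binomial())
    unname(coef(summary(fitj))[ncol(X) + 1, "z value"])
  }, numeric(1))
  expect_gte(cor(res@tstat[ok], wald), 0.99)
})

test_that("monomorphic SNPs surface as masked rows with NaN statistics", {
  d <- generateDataset(n = 80, m = 5, k = 2, seed = 26,
                       maf = c(0.3, 0.3, 0.3, 0, 0.4),
                       allowMonomorphic = TRUE)
  res <- snpAssociation(d, fitConfig(iters = 5e4, tol = 1e-9))
  expect_true(res@masked[4])
  expect_true(is.nan(res@tstat[4]))
  expect_true(is.nan(res@pvalue[4]))
  expect_false(any(res@masked[-4]))
  df <- as.data.frame(res)
  expect_identical(df$masked, c(0L, 0L, 0L, 1L, 0L))
})
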