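test_that("balanced intercept-only model keeps beta at zero", {
  X <- matrix(1, 8, 1)
  y <- rep(c(0, 1), 4)
  fit <- fitLogisticGD(list(X = X, y = y),
                       fitConfig(step = 0.7, iters = 25, keepTrace = TRUE))
  expect_identical(unname(coef(fit)), 0)
  # gradient is zero by symmetry at every iteration
  for (tr in fit@trace) expect_equal(tr$e, tr$delta)
})

test_that("one hand-computed update on a two-point dataset", {
  X <- matrix(c(1, -1), 2, 1)
  y <- c(1, 0)
  init <- fitLogisticGD(list(X = X, y = y), fitConfig(step = 1, iters = 1,
                                                      keepTrace = TRUE))
  # beta0 = alpha * X'(y - 1/2) = 0.5 + 0.5 = 1, then one update:
  # beta = 1 + (1 - sigma(1)) + sigma(-1) = 1.5378828
  expect_equal(init@trace[[1]]$u, c(1, -1))
  expect_equal(unname(coef(init)), 1.5378828, tolerance = 1e-7)
})

test_that("e/delta bookkeeping equals the closed-form gradient update", {
  d <- smallData(n = 80, m = 1, k = 2, seed = 3)
  cfg <- fitConfig(iters = 15, keepTrace = TRUE)
  fit <- fitLogisticGD(d, cfg)
  X <- covariateMatrix(d); y <- phenotype(d)
  alpha <- defaultStep(X)
  # independent closed-form recursion beta <- beta + alpha X'(y - sigma(X beta))
  beta <- alpha * drop(crossprod(X, y - 0.5))
  for (t in seq_len(fit@iterationsRun)) {
    tr <- fit@trace[[t]]
    u <- drop(X %*% beta)
    expect_equal(tr$u, unname(u), tolerance = 1e-10)
    expect_lt(max(abs((tr$e - tr$delta) -
                      alpha * drop(crossprod(X, y - plogis(u))))), 1e-12)
    beta <- beta + alpha * drop(crossprod(X, y - plogis(u)))
  }
  expect_equal(unname(coef(fit)), unname(beta), tolerance = 1e-10)
})

test_that("exact-mode descent reaches the maximum-likelihood solution", {
  d <- smallData(n = 250, m = 1, k = 3, seed = 11)
  fit <- convergedFit(d, tol = 1e-10)
  expect_true(fit@converged)
  ref <- glm(phenotype(d) ~ covariateMatrix(d) - 1, family = binomial())
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-4)
})

test_that("log-likelihood ascends monotonically at the default step", {
  d <- smallData(n = 120, m = 1, k = 2, seed = 9)
  X <- covariateMatrix(d); y <- phenotype(d)
  alpha <- defaultStep(X)
  ll <- function(b) sum(y * drop(X %*% b) -
                        log1p(exp(drop(X %*% b))))
  beta <- alpha * drop(crossprod(X, y - 0.5))
  prev <- ll(beta)
  for (t in 1:40) {
    beta <- beta + alpha * drop(crossprod(X, y - plogis(drop(X %*% beta))))
    cur <- ll(beta)
    expect_gte(cur, prev - 1e-12)
    prev <- cur
  }
})

test_that("oversized steps raise a named divergence error", {
  d <- smallData(n = 60, m = 1, k = 2, seed = 2)
  expect_error(fitLogisticGD(d, fitConfig(step = 1e308, iters = 10)),
               "diverged at iteration")
})

test_that("LUT-mode fit tracks the exact-mode fit", {
  d <- smallData(n = 200, m = 1, k = 2, seed = 5)
  lut <- buildSigmoidLUT(-4, 4, 2047)
  cfg <- fitConfig(iters = 60)
  fe <- fitLogisticGD(d, cfg)
  fl <- fitLogisticGD(d, fitConfig(iters = 60, sigmoidMode = "lut"), lut)
  expect_lt(max(abs(coef(fe) - coef(fl))), 1e-2)
  expect_error(fitLogisticGD(d, fitConfig(sigmoidMode = "lut")), "SigmoidLUT")
})

test_that("predicted probabilities respect mode-specific ranges", {
  d <- smallData(n = 100, m = 1, k = 2, seed = 6)
  X <- covariateMatrix(d)
  expect_equal(unname(predictProbabilities(X, rep(0, ncol(X)))),
               rep(0.5, 100))
  expect_error(predictProbabilities(X, c(0, 0)), "columns")
  fit <- convergedFit(d)
  pe <- predictProbabilities(X, coef(fit))
  expect_true(all(pe > 0 & pe < 1))
  lut <- buildSigmoidLUT(-4, 4, 2047)
  pl <- predictProbabilities(X, coef(fit), "lut", lut)
  expect_true(all(pl >= sigmoidExact(-4) & pl <= sigmoidExact(4)))
  inside <- abs(drop(X %*% coef(fit))) <= 4
  expect_lte(max(abs(pe[inside] - pl[inside])), 4.89e-4)
})

test_that("logistic weights are p - p^2, capped at 1/4", {
  expect_identical(computeWeights(0.5), 0.25)
  expect_equal(computeWeights(0.1), 0.09)
  expect_equal(max(computeWeights(seq(0, 1, by = 1e-4))), 0.25)
  expect_error(computeWeights(1.2), "\\[0, 1\\]")
})

test_that("fit is invariant to a change of design basis", {
  d <- smallData(n = 180, m = 1, k = 2, seed = 13)
  X <- covariateMatrix(d); y <- phenotype(d)
  set.seed(1)
  M <- diag(3) + matrix(rnorm(9, sd = 0.2), 3)
  f1 <- fitLogisticGD(list(X = X, y = y), fitConfig(iters = 2e5, tol = 1e-11))
  f2 <- fitLogisticGD(list(X = X %*% M, y = y),
                      fitConfig(iters = 2e5, tol = 1e-11))
  p1 <- unname(predictProbabilities(X, coef(f1)))
  p2 <- unname(predictProbabilities(X %*% M, coef(f2)))
  expect_equal(p1, p2, tolerance = 1e-8)
})
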