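#' Default gradient step from the spectral norm of the design
#'
#' The logistic log-likelihood gradient is Lipschitz with constant
#' `||X||_2^2 / 4`, so a step of `4 / ||X||_2^2` guarantees monotone ascent.
#'
#' @param X design matrix.
#' @return Positive step size.
#' @export
defaultStep <- function(X) {
  s <- svd(X, nu = 0, nv = 0)$d[1]
  4 / s^2
}

#' Fit configuration for gradient-descent logistic regression
#'
#' @param step positive gradient step alpha; `NULL` (default) selects
#'   `4 / ||X||_2^2` at fit time.
#' @param iters maximum number of iterations (default 30, mirroring a
#'   fixed-iteration schedule).
#' @param tol nonnegative gradient-norm tolerance; 0 (default) disables early
#'   stopping.
#' @param sigmoidMode `"exact"` or `"lut"`.
#' @param keepTrace record per-iteration `u`, `e`, `delta` vectors.
#' @return A list of class `FitConfig`.
#' @export
fitConfig <- function(step = NULL, iters = 30L, tol = 0,
                      sigmoidMode = c("exact", "lut"), keepTrace = FALSE) {
  sigmoidMode <- match.arg(sigmoidMode)
  if (!is.null(step) && !(is.numeric(step) && step > 0))
    stop("step must be positive")
  if (iters < 1) stop("iters must be >= 1")
  if (tol < 0) stop("tol must be nonnegative")
  structure(list(step = step, iters = as.integer(iters), tol = tol,
                 sigmoidMode = sigmoidMode, keepTrace = isTRUE(keepTrace)),
            class = "FitConfig")
}

#' Gradient-descent logistic regression with exact or LUT sigmoid
#'
#' Fits the covariate-only logistic model by plain gradient ascent on the
#' log-likelihood, the plaintext form of the encrypted regression step.
#' Initialization is `beta0 = alpha * X' (y - 1/2)` (the sigmoid at zero),
#' and each iteration computes the linear predictor `u = X beta`, then
#' updates `beta <- beta + e - delta` where `e = alpha * X' y` and
#' `delta = alpha * X' sigma(u)`, i.e. `beta <- beta + alpha X'(y -
#' sigma(u))` with `sigma` either the exact sigmoid or a clamped
#' nearest-node lookup table.
#'
#' @param data a [GwasDataset-class] (only covariates and outcome are used),
#'   or a list with elements `X` and `y`.
#' @param cfg a [fitConfig()] list.
#' @param lut a [SigmoidLUT-class]; required iff `cfg$sigmoidMode == "lut"`.
#' @return A [LogisticFit-class].
#' @examples
#' d <- generateDataset(n = 200, m = 1, k = 2, seed = 3)
#' fit <- fitLogisticGD(d, fitConfig(iters = 2000, tol = 1e-8))
#' coef(fit)
#' @export
fitLogisticGD <- function(data, cfg = fitConfig(), lut = NULL) {
  if (is(data, "GwasDataset")) {
    X <- covariateMatrix(data); y <- phenotype(data)
  } else {
    X <- as.matrix(data$X); y <- as.numeric(data$y)
  }
  if (cfg$sigmoidMode == "lut" && is.null(lut))
    stop("sigmoidMode 'lut' requires a SigmoidLUT")
  sig <- if (cfg$sigmoidMode == "lut") function(u) lutSigmoid(lut, u)
         else plogis
  alpha <- if (is.null(cfg$step)) defaultStep(X) else cfg$step
  e <- alpha * drop(crossprod(X, y))
  beta <- alpha * drop(crossprod(X, y - 0.5))
  trace <- if (cfg$keepTrace) vector("list", cfg$iters) else list()
  converged <- FALSE
  gnorm <- NA_real_
  it <- 0L
  for (it in seq_len(cfg$iters)) {
    u <- unname(drop(X %*% beta))
    if (any(!is.finite(u)) || any(!is.finite(beta)))
      stop(sprintf("gradient descent diverged at iteration %d (non-finite values); reduce the step", it))
    p <- sig(u)
    delta <- alpha * drop(crossprod(X, p))
    grad <- drop(crossprod(X, y - p))
    gnorm <- sqrt(sum(grad^2))
    if (cfg$keepTrace)
      trace[[it]] <- list(u = u, e = e, delta = delta)
    if (cfg$tol > 0 && gnorm <= cfg$tol) { converged <- TRUE; break }
    beta <- beta + e - delta
  }
  if (any(!is.finite(beta)))
    stop(sprintf("gradient descent diverged at iteration %d (non-finite coefficients); reduce the step", it))
  names(beta) <- colnames(X)
  new("LogisticFit", beta = beta, iterationsRun = it,
      converged = converged, gradNorm = gnorm,
      sigmoidMode = cfg$sigmoidMode,
      trace = if (cfg$keepTrace) trace[seq_len(it)] else list())
}

#' Predicted case probabilities
#'
#' `p_i = sigma(x_i' beta)` with the exact or lookup-table sigmoid.
#'
#' @param X design matrix with `length(beta)` columns.
#' @param beta coefficient vector.
#' @param sigmoidMode `"exact"` or `"lut"`.
#' @param lut [SigmoidLUT-class], required for LUT mode.
#' @return Probability vector of length `nrow(X)`.
#' @export
predictProbabilities <- function(X, beta, sigmoidMode = c("exact", "lut"),
                                 lut = NULL) {
  sigmoidMode <- match.arg(sigmoidMode)
  X <- as.matrix(X)
  if (ncol(X) != length(beta))
    stop(sprintf("X has %d columns but beta has length %d",
                 ncol(X), length(beta)))
  u <- drop(X %*% beta)
  if (sigmoidMode == "lut") {
    if (is.null(lut)) stop("LUT mode requires a SigmoidLUT")
    lutSigmoid(lut, u)
  } else plogis(u)
}

#' Logistic variance weights
#'
#' `w_i = p_i - p_i^2 = p_i (1 - p_i)`, the per-observation variance of a
#' Bernoulli outcome; bounded by 1/4.
#'
#' @param p probability vector with entries in `[0, 1]`.
#' @return Weights in `[0, 0.25]`.
#' @examples
#' computeWeights(c(0.5, 0.1))  # 0.25, 0.09
#' @export
computeWeights <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop("probabilities must lie in [0, 1]")
  p - p^2
}

#' Exact-mode log-likelihood (internal helper for ascent checks)
#' @noRd
logisticLogLik <- function(X, y, beta) {
  u <- drop(X %*% beta)
  sum(y * u - (pmax(u, 0) + log1p(exp(-abs(u)))))
}
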