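#' Weighted Gram matrix G = X' W X
#'
#' @param X design matrix, n by (k+1).
#' @param w nonnegative weight vector of length n (the diagonal of W, stored
#'   as a vector throughout).
#' @return Symmetric (k+1) by (k+1) matrix.
#' @export
computeGram <- function(X, w) {
  X <- as.matrix(X)
  if (length(w) != nrow(X))
    stop("length(w) must equal nrow(X)")
  if (any(w < 0)) stop("weights must be nonnegative")
  G <- crossprod(X, X * w)
  (G + t(G)) / 2  # enforce exact symmetry
}

#' Weighted cross-product A = X' W S
#'
#' @param X design matrix, n by (k+1).
#' @param w weight vector, length n.
#' @param S genotype matrix, n by m.
#' @return (k+1) by m matrix.
#' @export
computeA <- function(X, w, S) {
  X <- as.matrix(X); S <- as.matrix(S)
  if (length(w) != nrow(X) || nrow(S) != nrow(X))
    stop("X, w and S must agree on the number of samples")
  crossprod(X, S * w)
}

#' Taylor-series approximation of the Gram inverse
#'
#' Around a balanced dataset the Gram matrix is close to `I/4`, so with
#' `eps = 4G - I` the inverse expands as `G^-1 = 4 (I + eps)^-1 =
#' 4 * sum_t (-eps)^t`, convergent when the spectral radius of `eps` is
#' below 1. Order 0 returns `4I`, which is already a usable approximation
#' for well-balanced data.
#'
#' @param G symmetric square matrix.
#' @param order nonnegative truncation order.
#' @return Approximate inverse, same dimensions as `G`.
#' @examples
#' invertGTaylor(diag(2) / 4, order = 0)  # 4 I
#' @export
invertGTaylor <- function(G, order = 2L) {
  G <- as.matrix(G)
  if (nrow(G) != ncol(G)) stop("G must be square")
  if (max(abs(G - t(G))) > 1e-8 * max(1, max(abs(G))))
    stop("G must be symmetric")
  if (order < 0) stop("order must be nonnegative")
  k1 <- nrow(G)
  eps <- 4 * G - diag(k1)
  rho <- max(abs(eigen(eps, symmetric = TRUE, only.values = TRUE)$values))
  if (rho >= 1)
    warning(sprintf("Taylor series divergent: spectral radius of 4G - I is %.3g >= 1", rho))
  acc <- diag(k1)
  term <- diag(k1)
  for (t in seq_len(order)) {
    term <- -term %*% eps
    acc <- acc + term
  }
  4 * acc
}

#' Exact Gram inverse via Cholesky factorization
#'
#' @param G symmetric positive-definite matrix.
#' @return The inverse of `G`.
#' @export
invertGExact <- function(G) {
  G <- as.matrix(G)
  if (nrow(G) != ncol(G)) stop("G must be square")
  R <- tryCatch(chol(G), error = function(e)
    stop("G is not positive definite (singular Gram matrix): ",
         conditionMessage(e)))
  chol2inv(R)
}

#' Orthonormal basis for the design span
#'
#' The semi-parallel statistics are invariant to replacing the design
#' matrix by any basis of the same column span. Substituting the
#' orthonormal QR basis (`X' X = I`) brings the weighted Gram matrix close
#' to `I/4` (since the logistic weights are at most 1/4), which is the
#' regime where the Taylor-series inverse [invertGTaylor()] converges and
#' where `4I` is already a usable zeroth-order inverse.
#'
#' @param X design matrix with full column rank.
#' @return Matrix with orthonormal columns spanning the same space.
#' @export
orthonormalizeDesign <- function(X) {
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  qr.Q(qrX)
}

#' Score numerator (y - p)' S for every SNP
#'
#' At convergence of the covariate-only fit, the projected working response
#' reduces to `(y - p) / w` rescaled, and the per-SNP score numerator
#' simplifies to the residual-genotype inner product `(y - p)' S_j`.
#'
#' @param y binary outcome vector.
#' @param p fitted probability vector.
#' @param S genotype matrix, n by m.
#' @return Numeric vector of length m.
#' @export
statNumerator <- function(y, p, S) {
  S <- as.matrix(S)
  if (length(y) != length(p) || length(y) != nrow(S))
    stop("y, p and S must agree on the number of samples")
  drop(crossprod(S, y - p))
}

#' Score denominator s*^2 for every SNP
#'
#' `s*2_j = sum_i w_i S_ij^2 - A_j' Ginv A_j`: the squared norm of the
#' weighted genotype column minus the squared norm of its projection onto
#' the span of the weighted design. For binary S the element-wise square
#' `S * S` equals `S` and is skipped.
#'
#' @param w weight vector, length n.
#' @param S genotype matrix, n by m.
#' @param A cross-product from [computeA()].
#' @param Ginv Gram inverse (exact or Taylor).
#' @param binaryS use the `S * S = S` shortcut (default `TRUE`).
#' @param exactGinv set `TRUE` when `Ginv` is exact to enable the
#'   negative-denominator consistency check.
#' @return Numeric vector of length m, nonnegative up to round-off when
#'   `Ginv` is exact.
#' @export
statDenominator <- function(w, S, A, Ginv, binaryS = TRUE,
                            exactGinv = FALSE) {
  S <- as.matrix(S)
  if (length(w) != nrow(S)) stop("length(w) must equal nrow(S)")
  if (ncol(A) != ncol(S) || nrow(A) != nrow(Ginv))
    stop("dimension mismatch between S, A and Ginv")
  Ssq <- if (binaryS) S else S * S
  den <- drop(crossprod(Ssq, w)) - colSums(A * (Ginv %*% A))
  if (exactGinv) {
    tolNeg <- 1e-8 * max(1, max(abs(den)))
    if (any(den < -tolNeg))
      stop("negative denominator with exact Gram inverse: inconsistent inputs")
  }
  den
}

#' Wald-type statistic t = numerator / sqrt(denominator)
#'
#' Degenerate SNPs (denominator at or below `epsDen`) are flagged and
#' returned as `NaN`, never silently zeroed.
#'
#' @param numerator,denominator vectors from [statNumerator()] and
#'   [statDenominator()].
#' @param epsDen degeneracy threshold; default `1e-12 * n` scales with the
#'   sample size `n` (pass `n` via `nSamplesHint`, otherwise the raw 1e-12
#'   floor is used).
#' @param nSamplesHint optional sample count for the default threshold.
#' @return List with numeric `tstat` (NaN where masked) and logical
#'   `masked`.
#' @export
computeTstat <- function(numerator, denominator, epsDen = NULL,
                         nSamplesHint = NULL) {
  if (length(numerator) != length(denominator))
    stop("numerator and denominator must have equal length")
  if (is.null(epsDen))
    epsDen <- 1e-12 * if (is.null(nSamplesHint)) 1 else nSamplesHint
  tolNeg <- 1e-8 * max(1, max(abs(denominator)))
  if (any(denominator < -tolNeg))
    stop("negative denominator beyond numeric tolerance")
  masked <- denominator <= epsDen
  t <- rep(NaN, length(numerator))
  t[!masked] <- numerator[!masked] / sqrt(denominator[!masked])
  list(tstat = t, masked = masked)
}

#' Two-sided normal p-values from Wald statistics
#'
#' `p = 2 (1 - Phi(|t|))`, strictly decreasing in `|t|`; `NaN` statistics
#' (masked SNPs) propagate.
#'
#' @param t numeric vector of statistics.
#' @return p-values in `[0, 1]`.
#' @examples
#' tstatToPvalue(1.959964)  # 0.05
#' @export
tstatToPvalue <- function(t) {
  2 * pnorm(-abs(t))
}

#' Full projection-based oracle for the semi-parallel statistic
#'
#' The unsimplified form: builds the working response `z_i = x_i' beta +
#' (y_i - p_i) / w_i`, rescales by `sqrt(W)`, and projects both `z'` and
#' the weighted genotype columns onto the orthogonal complement of the span
#' of `sqrt(W) X` with an explicit projector. Serves as the independent
#' reference the simplified `(y - p)' S` / Gram path must agree with at
#' convergence.
#'
#' @param data a [GwasDataset-class].
#' @param beta coefficient vector of the covariate-only fit.
#' @param sigmoidMode,lut how probabilities are computed from `beta`.
#' @return List with `numerator`, `denominator` (length m), and the
#'   intermediates `z`, `zstarPrime`, `projector`.
#' @export
oracleSemiparallel <- function(data, beta, sigmoidMode = "exact",
                               lut = NULL) {
  X <- covariateMatrix(data)
  y <- phenotype(data)
  S <- genotypeMatrix(data)
  p <- predictProbabilities(X, beta, sigmoidMode, lut)
  w <- computeWeights(p)
  if (any(w <= 0))
    stop("oracle requires p strictly inside (0, 1) so all weights are positive")
  sw <- sqrt(w)
  z <- drop(X %*% beta) + (y - p) / w
  zp <- sw * z
  Xp <- X * sw
  Sp <- S * sw
  qrX <- qr(Xp)
  if (qrX$rank < ncol(Xp))
    stop("rank-deficient weighted design: sqrt(W) X does not have full column rank")
  Q <- qr.Q(qrX)
  P <- tcrossprod(Q)  # orthogonal projector onto span(sqrt(W) X)
  zstar <- zp - drop(P %*% zp)
  Sstar <- Sp - P %*% Sp
  list(numerator = drop(crossprod(Sstar, zstar)),
       denominator = colSums(Sstar^2),
       z = z, zstarPrime = zstar, projector = P)
}

#' End-to-end semi-parallel association scan
#'
#' Fits the covariate-only logistic model by gradient descent, then scores
#' every SNP at once through the simplified Gram identities: numerator
#' `(y - p)' S`, denominator `colsums(W S) - colsums(A * Ginv A)`,
#' statistic `t_j = numerator_j / sqrt(denominator_j)` and two-sided normal
#' p-values. Optionally appends the log-domain statistic.
#'
#' @param data a [GwasDataset-class].
#' @param cfg a [fitConfig()]; default runs exact-sigmoid descent for 30
#'   iterations.
#' @param lut optional [SigmoidLUT-class] for LUT mode.
#' @param ginv `"exact"` (Cholesky) or `"taylor"`.
#' @param taylorOrder truncation order for `ginv = "taylor"`.
#' @param logDomain append `logStat`/`sign` columns via [logDomainStat()].
#' @param logDomainControl list of arguments passed to [logDomainStat()]
#'   (e.g. `polyNum`, `polyDen`, or `exactLog = TRUE`).
#' @param fit optionally, a precomputed [LogisticFit-class] to reuse.
#' @return A [SnpStats-class].
#' @examples
#' d <- generateDataset(n = 120, m = 40, k = 2, seed = 11)
#' res <- snpAssociation(d, fitConfig(iters = 5000, tol = 1e-8))
#' head(as.data.frame(res))
#' @export
snpAssociation <- function(data, cfg = fitConfig(), lut = NULL,
                           ginv = c("exact", "taylor"), taylorOrder = 2L,
                           logDomain = FALSE, logDomainControl = list(),
                           fit = NULL) {
  ginv <- match.arg(ginv)
  if (is.null(fit)) fit <- fitLogisticGD(data, cfg, lut)
  X <- covariateMatrix(data)
  y <- phenotype(data)
  S <- genotypeMatrix(data)
  p <- predictProbabilities(X, fit@beta, cfg$sigmoidMode, lut)
  w <- computeWeights(p)
  G <- computeGram(X, w)
  A <- computeA(X, w, S)
  Ginv <- if (ginv == "exact") invertGExact(G)
          else invertGTaylor(G, taylorOrder)
  num <- statNumerator(y, p, S)
  den <- statDenominator(w, S, A, Ginv, binaryS = !isDosage(data),
                         exactGinv = (ginv == "exact"))
  den <- pmax(den, 0)
  ts <- computeTstat(num, den, nSamplesHint = nSamples(data))
  pv <- tstatToPvalue(ts$tstat)
  logStat <- numeric(0)
  sgn <- as.integer(sign(num))
  if (logDomain) {
    ld <- do.call(logDomainStat,
                  c(list(numerator = num, denominator = den,
                         masked = ts$masked), logDomainControl))
    logStat <- ld$logStat
    sgn <- ld$sign
  }
  new("SnpStats", snpIds = snpIds(data), numerator = num,
      denominator = den, tstat = ts$tstat, pvalue = pv,
      sign = sgn, masked = ts$masked, logStat = logStat)
}
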