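#' Matched quadratic branch of the smoothed log-absolute-value
#'
#' The smoothed log replaces `log|x|` inside `(-th, th)` by `a x^2 + b`;
#' matching value and first derivative at `x = th` gives the unique
#' solution `a = 1 / (2 th^2)`, `b = log(th) - 1/2`.
#'
#' @param th threshold in `(0, 1]` (1 allowed for testing the boundary).
#' @return List with `th`, `a`, `b`.
#' @examples
#' smoothedLogabsParams(1)  # a = 0.5, b = -0.5
#' @export
smoothedLogabsParams <- function(th = 0.05) {
  if (!(is.numeric(th) && length(th) == 1L && th > 0 && th <= 1))
    stop("th must lie in (0, 1]")
  list(th = th, a = 1 / (2 * th^2), b = log(th) - 0.5)
}

#' Smoothed log-absolute-value
#'
#' `log|x|` when `|x| > th`, otherwise the matched quadratic
#' `a x^2 + b`; even, continuous and differentiable everywhere, finite at 0
#' (value `b`). This is the objective the even polynomial approximates: it
#' removes the vertical asymptote at 0 that a polynomial cannot follow.
#'
#' @param x numeric vector.
#' @param params from [smoothedLogabsParams()].
#' @return Numeric vector.
#' @examples
#' p <- smoothedLogabsParams(0.5)
#' smoothedLogabs(exp(1), p)  # 1
#' smoothedLogabs(0.25, p)    # quadratic branch, about -1.0681
#' @export
smoothedLogabs <- function(x, params = smoothedLogabsParams()) {
  stopifnot(all(is.finite(x)))
  out <- numeric(length(x))
  outer_ <- abs(x) > params$th
  out[outer_] <- log(abs(x[outer_]))
  out[!outer_] <- params$a * x[!outer_]^2 + params$b
  out
}

#' Even least-squares polynomial approximation of the smoothed log
#'
#' Fits the smoothed log-absolute-value on a uniform grid over
#' `[lo, hi]` by least squares, restricted to even powers when
#' `even = TRUE` (degree 8 even keeps 5 free coefficients: powers 0, 2, 4,
#' 6, 8). The basis is evaluated in `x / basisScale` with `basisScale =
#' max(|lo|, |hi|)` so the normal equations stay well conditioned; the fit
#' uses a QR solve and errors if the basis is numerically rank-deficient.
#'
#' @param lo,hi fit range, `lo < hi`.
#' @param params from [smoothedLogabsParams()].
#' @param degree polynomial degree (default 8).
#' @param even restrict to even powers (default `TRUE`).
#' @param gridN number of grid nodes, at least `10 * degree` (default
#'   4096).
#' @return A [PolyApprox-class].
#' @export
fitLogabsPoly <- function(lo, hi, params = smoothedLogabsParams(),
                          degree = 8L, even = TRUE, gridN = 4096L) {
  if (!(lo < hi)) stop("lo must be < hi")
  if (gridN < 10 * degree) stop("gridN must be at least 10 * degree")
  degree <- as.integer(degree)
  powers <- if (even) seq(0L, degree, by = 2L) else 0:degree
  x <- seq(lo, hi, length.out = gridN)
  yv <- smoothedLogabs(x, params)
  bs <- max(abs(lo), abs(hi))
  B <- outer(x / bs, powers, `^`)
  fit <- lm.fit(B, yv)
  if (fit$rank < length(powers))
    stop("ill-conditioned polynomial basis; refit with an orthogonal basis or a narrower range")
  coefs <- fit$coefficients
  maxErr <- max(abs(drop(B %*% coefs) - yv))
  new("PolyApprox", degree = degree, coefficients = unname(coefs),
      powers = powers, fitLo = lo, fitHi = hi, even = even,
      basisScale = bs, maxError = maxErr)
}

#' Evaluate a fitted polynomial approximation
#'
#' @param poly a [PolyApprox-class].
#' @param x numeric vector.
#' @return Numeric vector `p(x)`.
#' @export
evalPoly <- function(poly, x) {
  drop(outer(x / poly@basisScale, poly@powers, `^`) %*% poly@coefficients)
}

#' Log-domain statistic: log|t| by polynomial subtraction
#'
#' Computes `logStat_j = P_num(numerator_j) - P_den(denominator_j) / 2`,
#' approximating `log|t_j| = log|numerator_j| - log(s*2_j) / 2`, together
#' with the exact numerator sign kept on the side (the log of an absolute
#' value discards it; p-values depend only on `|t|`, so they are
#' unaffected). `exp(logStat) * sign` reconstructs `t` up to the combined
#' polynomial fit error. With `exactLog = TRUE` the smoothed log itself is
#' used instead of its polynomial approximation, an identity for inputs
#' outside the quadratic branch.
#'
#' @param numerator,denominator vectors from the semi-parallel scan;
#'   denominator must be positive where unmasked.
#' @param polyNum,polyDen [PolyApprox-class] fits for the numerator and
#'   denominator ranges; defaults fit degree-8 even polynomials on
#'   `[-35, 35]` and `[-15, 15]`, covering the intermediate-variable
#'   ranges observed for this pipeline with a margin.
#' @param params smoothed-log parameters shared by the default fits.
#' @param exactLog bypass the polynomials and use [smoothedLogabs()].
#' @param masked logical vector; masked entries propagate as `NaN`.
#' @return List with numeric `logStat` and integer `sign`.
#' @export
logDomainStat <- function(numerator, denominator, polyNum = NULL,
                          polyDen = NULL, params = smoothedLogabsParams(),
                          exactLog = FALSE, masked = NULL) {
  if (length(numerator) != length(denominator))
    stop("numerator and denominator must have equal length")
  if (is.null(masked)) masked <- rep(FALSE, length(numerator))
  if (any(denominator[!masked] <= 0))
    stop("denominator must be positive where unmasked")
  if (exactLog) {
    ln <- smoothedLogabs(numerator, params)
    ld <- smoothedLogabs(denominator, params)
  } else {
    if (is.null(polyNum))
      polyNum <- fitLogabsPoly(-35, 35, params)
    if (is.null(polyDen))
      polyDen <- fitLogabsPoly(-15, 15, params)
    ln <- evalPoly(polyNum, numerator)
    ld <- evalPoly(polyDen, denominator)
  }
  logStat <- ln - ld / 2
  logStat[masked] <- NaN
  list(logStat = logStat, sign = as.integer(sign(numerator)))
}
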