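#' Exact logistic sigmoid
#'
#' Numerically stable `1 / (1 + exp(-x))`; saturates gracefully for large
#' `|x|`.
#'
#' @param x numeric vector.
#' @return Probabilities in (0, 1) (0/1 only at floating-point saturation).
#' @examples
#' sigmoidExact(0)      # 0.5
#' sigmoidExact(4)      # 0.9820138
#' @export
sigmoidExact <- function(x) {
  stopifnot(all(is.finite(x)))
  plogis(x)
}

#' Build a discretized sigmoid lookup table
#'
#' Tabulates the sigmoid on `d + 1` uniformly spaced nodes over
#' `[sigmaMin, sigmaMax]`, with `table[q] = sigmoid(sigmaMin +
#' (q/d) * (sigmaMax - sigmaMin))` for `q = 0..d`. This is the plaintext
#' analog of the test-polynomial encoding evaluated by blind rotation: the
#' encrypted form fuses the gradient step and design-matrix row into the
#' table, which is applied here in the update instead (algebraically
#' identical).
#'
#' @param sigmaMin,sigmaMax domain endpoints, `sigmaMin < sigmaMax`.
#'   Defaults -4 and 4: the observed linear-predictor range with a margin.
#' @param d number of discretization intervals (>= 1); see [dFromRing()] for
#'   the ring-dimension-derived default used by the encrypted setting.
#' @return A [SigmoidLUT-class].
#' @examples
#' lut <- buildSigmoidLUT(-4, 4, 2)
#' lut@table  # sigmoid at -4, 0, 4
#' @export
buildSigmoidLUT <- function(sigmaMin = -4, sigmaMax = 4, d = dFromRing()) {
  if (!is.numeric(d) || length(d) != 1L || d < 1)
    stop("d must be a positive count")
  if (!(sigmaMin < sigmaMax))
    stop("sigmaMin must be < sigmaMax")
  d <- as.integer(d)
  nodes <- sigmaMin + (0:d) / d * (sigmaMax - sigmaMin)
  new("SigmoidLUT", sigmaMin = sigmaMin, sigmaMax = sigmaMax, d = d,
      table = plogis(nodes))
}

#' Discretization levels from ring dimension
#'
#' The number of representable sigmoid levels when a test polynomial of ring
#' dimension `N` interleaves `cols` design-matrix columns:
#' `d = floor(N / cols) - 1`. `cols` is the number of columns of the design
#' matrix (covariates plus intercept), passed explicitly.
#'
#' @param N ring dimension (default 8192).
#' @param cols number of design-matrix columns (default 4).
#' @return Integer level count.
#' @examples
#' dFromRing(8192, 4)  # 2047
#' @export
dFromRing <- function(N = 8192, cols = 4) {
  stopifnot(N >= 1, cols >= 1)
  as.integer(floor(N / cols) - 1)
}

#' Evaluate the lookup-table sigmoid
#'
#' Maps `x` to the nearest table node: `q = round((x - sigmaMin) /
#' (sigmaMax - sigmaMin) * d)` with round-half-even, clamped to `[0, d]`
#' (out-of-range inputs saturate at the endpoint values, mirroring the
#' clamped blind-rotate evaluation).
#'
#' @param lut a [SigmoidLUT-class].
#' @param x numeric vector of finite values.
#' @return Tabulated sigmoid values.
#' @examples
#' lut <- buildSigmoidLUT(-4, 4, 2046)
#' lutSigmoid(lut, 0)    # 0.5 (even d, symmetric range)
#' lutSigmoid(lut, -10)  # clamps to sigmoid(-4)
#' @export
lutSigmoid <- function(lut, x) {
  stopifnot(is(lut, "SigmoidLUT"), all(is.finite(x)))
  q <- round((x - lut@sigmaMin) / (lut@sigmaMax - lut@sigmaMin) * lut@d)
  q <- pmin(pmax(q, 0), lut@d)
  lut@table[q + 1L]
}

#' Number of ciphertext blocks needed to pack m SNP slots
#'
#' With `slots` values packed per ciphertext, a row of m SNP entries
#' occupies `ceiling(m / slots)` blocks; each regression row then costs that
#' many external products.
#'
#' @param m number of SNPs.
#' @param slots slots per ciphertext (default 4096, half the ring dimension
#'   used at this stage).
#' @return Integer block count.
#' @examples
#' packingBlocks(10643)  # 3
#' @export
packingBlocks <- function(m, slots = 4096) {
  stopifnot(m >= 1, slots >= 1)
  as.integer(ceiling(m / slots))
}
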