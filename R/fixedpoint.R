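#' Variables tracked by the fixed-point machinery, in report order
#' @noRd
.rangeVariables <- c("p", "W", "z*", "G", "A", "s*2", "r_i", "p-value")

#' Variables that are quantized (the p-value is computed client-side)
#' @noRd
.quantVariables <- c("p", "W", "z*", "G", "A", "s*2", "r_i")

#' Derive a torus scale factor from a value range
#'
#' Maps the widest absolute value of a variable onto the usable torus
#' fraction: `scale = budget / max(|minVal|, |maxVal|)`. With the
#' linear-predictor range extended to `[-4, 4]` and the negacyclic budget
#' of 1/4, this yields the scale 1/16.
#'
#' @param minVal,maxVal observed or assumed variable range, `minVal <
#'   maxVal`.
#' @param budget usable torus fraction (default 1/4).
#' @return Positive scale factor.
#' @examples
#' deriveScale(-4, 4)  # 1/16
#' @export
deriveScale <- function(minVal, maxVal, budget = 0.25) {
  if (!(maxVal > minVal)) stop("zero-width or inverted range")
  if (!(budget > 0)) stop("budget must be positive")
  amp <- max(abs(minVal), abs(maxVal))
  if (amp == 0) stop("zero-width range: both endpoints are 0")
  budget / amp
}

#' Construct a FixedPointSpec
#'
#' @param scale positive multiplier to torus units.
#' @param fracBits fractional bits f; values are rounded to the `2^-f`
#'   grid with round-half-even.
#' @param torusBudget usable torus fraction, in (0, 1/2]; default 1/4
#'   (negacyclic constraint).
#' @param overflowPolicy `"none"`, `"wrap"` or `"strict"`.
#' @return A [FixedPointSpec-class].
#' @export
fixedPointSpec <- function(scale = 1, fracBits = 20L, torusBudget = 0.25,
                           overflowPolicy = c("none", "wrap", "strict")) {
  overflowPolicy <- match.arg(overflowPolicy)
  new("FixedPointSpec", scale = scale, fracBits = as.integer(fracBits),
      torusBudget = torusBudget, overflowPolicy = overflowPolicy)
}

#' Quantize values onto the torus grid
#'
#' Multiplies by the scale, rounds to the dyadic grid `2^-f`
#' (round-half-even), then applies the overflow policy: `"wrap"` reduces
#' modulo 1 into `[-1/2, 1/2)` (exact mod-1 arithmetic), `"strict"` raises
#' an error naming the variable when the magnitude exceeds the torus
#' budget, `"none"` leaves the grid value untouched.
#'
#' @param x numeric vector or matrix (dimensions preserved).
#' @param spec a [FixedPointSpec-class].
#' @param name variable name used in overflow errors.
#' @return Torus-grid values, same shape as `x`.
#' @examples
#' sp <- fixedPointSpec(scale = 1, fracBits = 4, overflowPolicy = "wrap")
#' quantizeValues(0.75, sp)  # -0.25
#' @export
quantizeValues <- function(x, spec, name = "value") {
  stopifnot(is(spec, "FixedPointSpec"), all(is.finite(x)))
  v <- x * spec@scale
  g <- 2^spec@fracBits
  t <- round(v * g) / g
  if (spec@overflowPolicy == "wrap") {
    t <- t - floor(t + 0.5)
  } else if (spec@overflowPolicy == "strict") {
    if (any(abs(t) > spec@torusBudget))
      stop(sprintf("fixed-point overflow in variable '%s': |scaled| up to %.4g exceeds torus budget %g",
                   name, max(abs(t)), spec@torusBudget))
  }
  t
}

#' @rdname quantizeValues
#' @param t torus-grid values from [quantizeValues()].
#' @export
dequantizeValues <- function(t, spec) {
  stopifnot(is(spec, "FixedPointSpec"))
  t / spec@scale
}

#' Round-trip a value through the torus grid
#' @noRd
.requantize <- function(x, spec, name) {
  dequantizeValues(quantizeValues(x, spec, name), spec)
}

#' Simulate the ranges of the pipeline's intermediate variables
#'
#' Runs the exact-arithmetic pipeline once and reports average, standard
#' deviation, minimum and maximum for the eight tracked variables, in
#' order: `p`, `W`, `z*` (score numerator), `G`, `A`, `s*2`, `r_i`
#' (statistic) and `p-value`. These observed ranges are what the scale
#' factors of the encrypted evaluation are derived from; masked SNPs are
#' excluded from the `r_i` and `p-value` rows.
#'
#' @param data a [GwasDataset-class].
#' @param cfg a [fitConfig()].
#' @param lut optional [SigmoidLUT-class] for LUT mode.
#' @return `data.frame` with columns `variable`, `avg`, `stdev`, `min`,
#'   `max`.
#' @export
simulateRanges <- function(data, cfg = fitConfig(), lut = NULL) {
  fit <- fitLogisticGD(data, cfg, lut)
  X <- covariateMatrix(data)
  y <- phenotype(data)
  S <- genotypeMatrix(data)
  p <- predictProbabilities(X, fit@beta, cfg$sigmoidMode, lut)
  w <- computeWeights(p)
  G <- computeGram(X, w)
  A <- computeA(X, w, S)
  Ginv <- invertGExact(G)
  num <- statNumerator(y, p, S)
  den <- pmax(statDenominator(w, S, A, Ginv, binaryS = !isDosage(data),
                              exactGinv = TRUE), 0)
  ts <- computeTstat(num, den, nSamplesHint = nSamples(data))
  pv <- tstatToPvalue(ts$tstat)
  vals <- list(p, w, num, as.vector(G), as.vector(A), den,
               ts$tstat[!ts$masked], pv[!ts$masked])
  names(vals) <- .rangeVariables
  do.call(rbind, lapply(.rangeVariables, function(v) {
    x <- vals[[v]]
    data.frame(variable = v, avg = mean(x), stdev = sd(x),
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  }))
}

#' Two-pass scale derivation from simulated ranges
#'
#' First pass: [simulateRanges()] on the input itself. Second pass: one
#' [fixedPointSpec()] per quantized variable with
#' `scale = budget / max(|min|, |max|)`, the same rule the encrypted
#' pipeline's scales were derived with from plaintext simulation.
#'
#' @param data,cfg,lut as in [simulateRanges()].
#' @param fracBits fractional bits shared by all variables.
#' @param budget torus budget (default 1/4).
#' @param overflowPolicy policy shared by all variables.
#' @return Named list of [FixedPointSpec-class], one per variable in
#'   `c("p", "W", "z*", "G", "A", "s*2", "r_i")`.
#' @export
twoPassSpecs <- function(data, cfg = fitConfig(), lut = NULL,
                         fracBits = 20L, budget = 0.25,
                         overflowPolicy = "none") {
  rng <- simulateRanges(data, cfg, lut)
  specs <- lapply(.quantVariables, function(v) {
    row <- rng[rng$variable == v, ]
    amp <- max(abs(row$min), abs(row$max))
    sc <- if (amp == 0) 1 else budget / amp
    fixedPointSpec(scale = sc, fracBits = fracBits, torusBudget = budget,
                   overflowPolicy = overflowPolicy)
  })
  names(specs) <- .quantVariables
  specs
}

#' Uniform specs (same scale and bits for every variable)
#'
#' @param scale,fracBits,budget,overflowPolicy shared spec fields.
#' @return Named list of [FixedPointSpec-class] per quantized variable.
#' @export
uniformSpecs <- function(scale = 1, fracBits = 53L, budget = 0.25,
                         overflowPolicy = "none") {
  specs <- lapply(.quantVariables, function(v)
    fixedPointSpec(scale, fracBits, budget, overflowPolicy))
  names(specs) <- .quantVariables
  specs
}

#' Run the pipeline with fixed-point quantization of every intermediate
#'
#' Executes the association scan with the LUT sigmoid in the regression
#' and a quantize/dequantize round trip applied to each named intermediate
#' (`p`, `W`, `G`, `A`, numerator `z*`, denominator `s*2`, statistic
#' `r_i`) as it is formed — emulating ciphertext-level granularity, not
#' rounding inside BLAS accumulations. Strict-policy overflows name the
#' offending variable.
#'
#' @param data a [GwasDataset-class].
#' @param cfg a [fitConfig()]; the regression uses the LUT sigmoid
#'   regardless of `cfg$sigmoidMode`, mirroring the encrypted evaluation.
#' @param specs named list of [FixedPointSpec-class] covering every
#'   variable in `c("p", "W", "z*", "G", "A", "s*2", "r_i")`; see
#'   [twoPassSpecs()] and [uniformSpecs()].
#' @param lut a [SigmoidLUT-class] (required).
#' @return A [SnpStats-class].
#' @export
runQuantized <- function(data, cfg = fitConfig(), specs = uniformSpecs(),
                         lut = buildSigmoidLUT()) {
  missing_ <- setdiff(.quantVariables, names(specs))
  if (length(missing_) > 0)
    stop("specs must cover every tracked variable; missing: ",
         paste(missing_, collapse = ", "))
  cfgLut <- cfg
  cfgLut$sigmoidMode <- "lut"
  fit <- fitLogisticGD(data, cfgLut, lut)
  X <- covariateMatrix(data)
  y <- phenotype(data)
  S <- genotypeMatrix(data)
  p <- predictProbabilities(X, fit@beta, "lut", lut)
  p <- .requantize(p, specs[["p"]], "p")
  w <- .requantize(computeWeights(pmin(pmax(p, 0), 1)), specs[["W"]], "W")
  w <- pmax(w, 0)
  G <- .requantize(computeGram(X, w), specs[["G"]], "G")
  A <- .requantize(computeA(X, w, S), specs[["A"]], "A")
  Ginv <- invertGExact(G)
  num <- .requantize(statNumerator(y, p, S), specs[["z*"]], "z*")
  den <- statDenominator(w, S, A, Ginv, binaryS = !isDosage(data))
  den <- pmax(.requantize(den, specs[["s*2"]], "s*2"), 0)
  ts <- computeTstat(num, den, nSamplesHint = nSamples(data))
  t <- ts$tstat
  t[!ts$masked] <- .requantize(t[!ts$masked], specs[["r_i"]], "r_i")
  pv <- tstatToPvalue(t)
  new("SnpStats", snpIds = snpIds(data), numerator = num,
      denominator = den, tstat = t, pvalue = pv,
      sign = as.integer(sign(num)), masked = ts$masked,
      logStat = numeric(0))
}

#' Compare the quantized pipeline against exact arithmetic
#'
#' Runs the unquantized pipeline (sigmoid per `cfg$sigmoidMode`) and the
#' quantized LUT pipeline on the same data and reports per-SNP agreement
#' of the statistic vectors: the maximum absolute difference and the
#' Pearson correlation across unmasked SNPs.
#'
#' @param data,cfg,lut as in [runQuantized()].
#' @param specs per-variable specs, or `NULL` to derive them two-pass via
#'   [twoPassSpecs()] with `fracBits`.
#' @param fracBits used only when `specs` is `NULL`.
#' @return List with `exact` and `quantized` [SnpStats-class] objects,
#'   `maxAbsDiff` and `pearson`.
#' @export
compareQuantizedVsExact <- function(data, cfg = fitConfig(),
                                    lut = buildSigmoidLUT(),
                                    specs = NULL, fracBits = 20L) {
  if (is.null(specs))
    specs <- twoPassSpecs(data, cfg, lut, fracBits = fracBits)
  exact <- snpAssociation(data, cfg, lut = lut, ginv = "exact")
  quant <- runQuantized(data, cfg, specs, lut)
  ok <- !(exact@masked | quant@masked)
  list(exact = exact, quantized = quant,
       maxAbsDiff = max(abs(exact@tstat[ok] - quant@tstat[ok])),
       pearson = cor(exact@tstat[ok], quant@tstat[ok]))
}

#' Check observed ranges against fixed-point budgets
#'
#' One warning string per variable whose observed extreme, once scaled,
#' exceeds the torus budget of its spec — the check the encrypted pipeline
#' needs before committing to a set of scales.
#'
#' @param reports `data.frame` from [simulateRanges()].
#' @param specs named list of [FixedPointSpec-class].
#' @return Character vector of warnings (empty when all variables fit).
#' @export
checkOverflow <- function(reports, specs) {
  out <- character(0)
  for (v in intersect(reports$variable, names(specs))) {
    row <- reports[reports$variable == v, ]
    sp <- specs[[v]]
    peak <- max(abs(row$min), abs(row$max)) * sp@scale
    if (peak > sp@torusBudget)
      out <- c(out, sprintf(
        "variable '%s': scaled magnitude %.4g exceeds torus budget %g",
        v, peak, sp@torusBudget))
  }
  out
}
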