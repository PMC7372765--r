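#' @importFrom methods new validObject is setClass setValidity setMethod
#'   setGeneric show slot
#' @importFrom stats rnorm rbinom pnorm qlogis glm binomial coef runif sd
#'   plogis lm.fit cor
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' GwasDataset: genotypes, covariates and outcome for association testing
#'
#' A container for the inputs of the semi-parallel association pipeline,
#' extending [SummarizedExperiment::SummarizedExperiment]. The single assay
#' `"genotype"` holds the SNP-by-sample matrix (m SNPs as rows, n patients as
#' columns, binary 0/1 presence coding unless dosage mode is enabled);
#' `colData` carries the covariate columns and the binary outcome `y`. The
#' intercept column is part of the covariate matrix returned by
#' [covariateMatrix()], so a dataset with `k` measured covariates has a
#' design matrix with `k + 1` columns.
#'
#' @slot dosage logical scalar; when `TRUE` genotype entries may be counts
#'   (e.g. 0/1/2) and the binary element-wise-square shortcut is disabled
#'   downstream.
#'
#' @seealso [GwasDataset()] for the constructor, [generateDataset()] and
#'   [idashLike()] for simulation, [readInputs()] for file ingestion.
#' @export
setClass("GwasDataset",
  contains = "SummarizedExperiment",
  slots = c(dosage = "logical"),
  prototype = prototype(dosage = FALSE)
)

setValidity("GwasDataset", function(object) {
  msg <- character()
  if (!"genotype" %in% assayNames(object))
    msg <- c(msg, "assay 'genotype' is required")
  cd <- colData(object)
  if (!"y" %in% colnames(cd))
    msg <- c(msg, "colData column 'y' (binary outcome) is required")
  if (length(msg) > 0) return(msg)
  y <- cd$y
  if (anyNA(y) || !all(y %in% c(0, 1)))
    msg <- c(msg, "outcome y must be 0/1 with no missing values")
  S <- assay(object, "genotype")
  if (anyNA(S))
    msg <- c(msg, "genotype matrix contains missing values")
  else if (!object@dosage && !all(S == 0 | S == 1))
    msg <- c(msg, "genotype entries must be 0/1 unless dosage mode is enabled")
  k1 <- sum(!colnames(cd) %in% "y") + 1L  # covariates + intercept
  if (ncol(object) < k1 + 1L)
    msg <- c(msg, sprintf("need at least k+2 = %d samples, got %d",
                          k1 + 1L, ncol(object)))
  if (length(msg) > 0) msg else TRUE
})

#' Construct a GwasDataset
#'
#' @param X numeric matrix, n samples by (k+1) columns whose first column is
#'   the intercept (all ones). Column names are kept; the intercept column is
#'   named `"(Intercept)"` if unnamed.
#' @param y binary outcome vector of length n.
#' @param S genotype matrix, n samples by m SNPs, binary 0/1 (or counts when
#'   `dosage = TRUE`).
#' @param snpIds character vector of SNP identifiers, length m; defaults to
#'   `colnames(S)` or `snp1..snpm`.
#' @param sampleIds sample identifiers, length n.
#' @param dosage logical; allow non-binary genotype entries.
#' @return A [GwasDataset-class] object.
#' @examples
#' d <- generateDataset(n = 40, m = 10, k = 2, seed = 1)
#' d
#' dim(genotypeMatrix(d))
#' @export
GwasDataset <- function(X, y, S, snpIds = NULL, sampleIds = NULL,
                        dosage = FALSE) {
  X <- as.matrix(X)
  S <- as.matrix(S)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n || nrow(S) != n)
    stop("X, y and S must agree on the number of samples (rows)")
  if (!all(X[, 1] == 1))
    stop("first column of X must be the intercept (all ones)")
  cn <- colnames(X)
  if (is.null(cn)) cn <- c("(Intercept)", paste0("cov", seq_len(ncol(X) - 1L)))
  if (is.na(cn[1]) || cn[1] == "") cn[1] <- "(Intercept)"
  colnames(X) <- cn
  if (is.null(snpIds)) snpIds <- colnames(S)
  if (is.null(snpIds)) snpIds <- paste0("snp", seq_len(ncol(S)))
  if (length(snpIds) != ncol(S))
    stop("snpIds must have one entry per SNP column of S")
  if (is.null(sampleIds)) sampleIds <- rownames(X)
  if (is.null(sampleIds)) sampleIds <- paste0("sample", seq_len(n))
  cd <- DataFrame(X[, -1, drop = FALSE], row.names = sampleIds)
  cd$y <- y
  geno <- t(S)
  dimnames(geno) <- list(snpIds, sampleIds)
  se <- SummarizedExperiment(assays = list(genotype = geno), colData = cd)
  new("GwasDataset", se, dosage = isTRUE(dosage))
}

#' SigmoidLUT: discretized sigmoid lookup table
#'
#' Uniform tabulation of the logistic sigmoid over `[sigmaMin, sigmaMax]` on
#' `d + 1` nodes, emulating the test-polynomial encoding used by
#' blind-rotate function evaluation in torus-based homomorphic schemes. The
#' table stores bare sigmoid values; the gradient step and design-matrix
#' entries are applied in the update, which is algebraically identical to
#' fusing them into the table.
#'
#' @slot sigmaMin,sigmaMax numeric domain endpoints.
#' @slot d integer number of discretization intervals.
#' @slot table numeric vector of length `d + 1`.
#' @seealso [buildSigmoidLUT()], [lutSigmoid()], [dFromRing()]
#' @export
setClass("SigmoidLUT",
  slots = c(sigmaMin = "numeric", sigmaMax = "numeric",
            d = "integer", table = "numeric"))

setValidity("SigmoidLUT", function(object) {
  msg <- character()
  if (!(object@sigmaMin < object@sigmaMax))
    msg <- c(msg, "sigmaMin must be < sigmaMax")
  if (object@d < 1L) msg <- c(msg, "d must be >= 1")
  if (length(object@table) != object@d + 1L)
    msg <- c(msg, "table must have d + 1 entries")
  if (any(diff(object@table) <= 0))
    msg <- c(msg, "table must be strictly increasing")
  if (any(object@table <= 0 | object@table >= 1))
    msg <- c(msg, "table values must lie in (0, 1)")
  if (length(msg) > 0) msg else TRUE
})

#' LogisticFit: result of gradient-descent logistic regression
#'
#' @slot beta numeric coefficient vector, length k+1 (intercept first).
#' @slot iterationsRun integer number of update iterations performed.
#' @slot converged logical; `TRUE` if the gradient-norm tolerance was met.
#' @slot gradNorm numeric final Euclidean norm of the gradient.
#' @slot sigmoidMode `"exact"` or `"lut"`.
#' @slot trace list of per-iteration records (`u`, `e`, `delta`), possibly
#'   empty.
#' @seealso [fitLogisticGD()]
#' @export
setClass("LogisticFit",
  slots = c(beta = "numeric", iterationsRun = "integer",
            converged = "logical", gradNorm = "numeric",
            sigmoidMode = "character", trace = "list"))

#' SnpStats: per-SNP semi-parallel association statistics
#'
#' Holds the numerator (y - p)' S, the denominator s*^2, the Wald-type
#' statistic t = numerator / sqrt(denominator), two-sided normal p-values,
#' the numerator sign, and a mask flag for degenerate SNPs (denominator at or
#' below the numeric threshold; their `tstat`/`pvalue` are `NaN`, never
#' silently zeroed). Optional log-domain columns are present when the
#' log-domain path was requested.
#'
#' @slot snpIds character, SNP identifiers.
#' @slot numerator,denominator,tstat,pvalue numeric vectors, length m.
#' @slot sign integer vector in \{-1, 0, 1\}.
#' @slot masked logical vector, `TRUE` for degenerate SNPs.
#' @slot logStat numeric vector (length m or 0 when not computed).
#' @seealso [snpAssociation()], [writeResults()]
#' @export
setClass("SnpStats",
  slots = c(snpIds = "character", numerator = "numeric",
            denominator = "numeric", tstat = "numeric", pvalue = "numeric",
            sign = "integer", masked = "logical", logStat = "numeric"))

setValidity("SnpStats", function(object) {
  m <- length(object@numerator)
  lens <- c(length(object@snpIds), length(object@denominator),
            length(object@tstat), length(object@pvalue),
            length(object@sign), length(object@masked))
  if (!all(lens == m)) return("all statistic vectors must share length m")
  if (!(length(object@logStat) %in% c(0L, m)))
    return("logStat must be empty or length m")
  ok <- !object@masked
  if (any(object@pvalue[ok] < 0 | object@pvalue[ok] > 1, na.rm = TRUE))
    return("p-values must lie in [0, 1]")
  TRUE
})

#' FixedPointSpec: torus fixed-point encoding of one pipeline variable
#'
#' A scale factor maps engineering units to torus units; values are then
#' rounded to the dyadic grid `2^-fracBits`. The usable torus fraction
#' defaults to 1/4 because negacyclic function evaluation restricts
#' plaintexts to half of the torus.
#'
#' @slot scale positive numeric multiplier.
#' @slot fracBits integer number of fractional bits f (grid `2^-f`).
#' @slot torusBudget numeric in (0, 1/2], usable torus fraction.
#' @slot overflowPolicy `"none"` (grid rounding only), `"wrap"` (reduce
#'   modulo 1 into `[-1/2, 1/2)`) or `"strict"` (error on budget overflow).
#' @seealso [fixedPointSpec()], [quantizeValues()], [deriveScale()]
#' @export
setClass("FixedPointSpec",
  slots = c(scale = "numeric", fracBits = "integer",
            torusBudget = "numeric", overflowPolicy = "character"))

setValidity("FixedPointSpec", function(object) {
  msg <- character()
  if (!(object@scale > 0)) msg <- c(msg, "scale must be positive")
  if (object@fracBits < 1L) msg <- c(msg, "fracBits must be >= 1")
  if (!(object@torusBudget > 0 && object@torusBudget <= 0.5))
    msg <- c(msg, "torusBudget must lie in (0, 1/2]")
  if (!object@overflowPolicy %in% c("none", "wrap", "strict"))
    msg <- c(msg, "overflowPolicy must be 'none', 'wrap' or 'strict'")
  if (length(msg) > 0) msg else TRUE
})

#' PolyApprox: even least-squares polynomial approximation
#'
#' Least-squares fit of a target function (here the smoothed
#' log-absolute-value) on a uniform grid over `[fitLo, fitHi]`, restricted to
#' even powers when `even = TRUE`. The basis is evaluated in units of
#' `basisScale` (the largest absolute endpoint) for conditioning.
#'
#' @slot degree integer polynomial degree.
#' @slot coefficients numeric, one per retained power.
#' @slot powers integer vector of retained powers.
#' @slot fitLo,fitHi numeric fit range.
#' @slot even logical.
#' @slot basisScale numeric.
#' @slot maxError numeric achieved maximum absolute fit error on the grid.
#' @seealso [fitLogabsPoly()], [evalPoly()]
#' @export
setClass("PolyApprox",
  slots = c(degree = "integer", coefficients = "numeric", powers = "integer",
            fitLo = "numeric", fitHi = "numeric", even = "logical",
            basisScale = "numeric", maxError = "numeric"))
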