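#' Accessors for GwasDataset
#'
#' `covariateMatrix()` returns the n-by-(k+1) design matrix including the
#' leading intercept column; `phenotype()` the binary outcome vector;
#' `genotypeMatrix()` the patient-major n-by-m genotype matrix;
#' `snpIds()` the SNP identifiers; `nSnps()`, `nSamples()` and
#' `nCovariates()` the dimensions (k counts measured covariates, excluding
#' the intercept).
#'
#' @param object a [GwasDataset-class].
#' @return See individual descriptions above.
#' @examples
#' d <- generateDataset(n = 30, m = 5, k = 2, seed = 7)
#' dim(covariateMatrix(d))  # 30 x 3
#' nSnps(d)
#' @name gwas-accessors
NULL

#' @rdname gwas-accessors
#' @export
setGeneric("covariateMatrix", function(object) standardGeneric("covariateMatrix"))

#' @rdname gwas-accessors
#' @export
setMethod("covariateMatrix", "GwasDataset", function(object) {
  cd <- colData(object)
  covs <- cd[, !colnames(cd) %in% "y", drop = FALSE]
  X <- cbind(`(Intercept)` = rep(1, nrow(covs)), as.matrix(covs))
  rownames(X) <- rownames(cd)
  X
})

#' @rdname gwas-accessors
#' @export
setGeneric("phenotype", function(object) standardGeneric("phenotype"))

#' @rdname gwas-accessors
#' @export
setMethod("phenotype", "GwasDataset", function(object) {
  y <- colData(object)$y
  names(y) <- rownames(colData(object))
  y
})

#' @rdname gwas-accessors
#' @export
setGeneric("genotypeMatrix", function(object) standardGeneric("genotypeMatrix"))

#' @rdname gwas-accessors
#' @export
setMethod("genotypeMatrix", "GwasDataset", function(object) {
  t(assay(object, "genotype"))
})

#' @rdname gwas-accessors
#' @export
setGeneric("snpIds", function(object) standardGeneric("snpIds"))

#' @rdname gwas-accessors
#' @export
setMethod("snpIds", "GwasDataset", function(object) rownames(object))

#' @rdname gwas-accessors
#' @export
setMethod("snpIds", "SnpStats", function(object) object@snpIds)

#' @rdname gwas-accessors
#' @export
setGeneric("nSnps", function(object) standardGeneric("nSnps"))

#' @rdname gwas-accessors
#' @export
setMethod("nSnps", "GwasDataset", function(object) nrow(object))

#' @rdname gwas-accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname gwas-accessors
#' @export
setMethod("nSamples", "GwasDataset", function(object) ncol(object))

#' @rdname gwas-accessors
#' @export
setGeneric("nCovariates", function(object) standardGeneric("nCovariates"))

#' @rdname gwas-accessors
#' @export
setMethod("nCovariates", "GwasDataset", function(object) {
  sum(!colnames(colData(object)) %in% "y")
})

#' @rdname gwas-accessors
#' @export
setGeneric("isDosage", function(object) standardGeneric("isDosage"))

#' @rdname gwas-accessors
#' @export
setMethod("isDosage", "GwasDataset", function(object) object@dosage)

#' Coefficients of a gradient-descent logistic fit
#'
#' @param object a [LogisticFit-class].
#' @param ... ignored.
#' @return Named numeric vector of regression coefficients.
#' @export
setMethod("coef", "LogisticFit", function(object, ...) object@beta)

#' Convert SnpStats to a data.frame
#'
#' Columns: `snp_id`, `numerator`, `denominator`, `tstat`, `pvalue`,
#' `masked` and, when the log-domain path was run, `log_stat` and `sign`.
#'
#' @param x a [SnpStats-class].
#' @param ... ignored.
#' @return A `data.frame` with one row per SNP in input order.
#' @export
as.data.frame.SnpStats <- function(x, ...) {
  df <- data.frame(
    snp_id = x@snpIds,
    numerator = x@numerator,
    denominator = x@denominator,
    tstat = x@tstat,
    pvalue = x@pvalue,
    masked = as.integer(x@masked),
    stringsAsFactors = FALSE
  )
  if (length(x@logStat) > 0) {
    df$log_stat <- x@logStat
    df$sign <- x@sign
  }
  df
}

setMethod("show", "GwasDataset", function(object) {
  cat(sprintf(
    "GwasDataset: %d SNPs x %d samples, %d covariates (+ intercept)%s\n",
    nSnps(object), nSamples(object), nCovariates(object),
    if (object@dosage) ", dosage genotypes" else ", binary genotypes"))
  cat(sprintf("  cases: %d / %d\n", sum(phenotype(object)), nSamples(object)))
})

setMethod("show", "SigmoidLUT", function(object) {
  cat(sprintf("SigmoidLUT: %d levels on [%g, %g]\n",
              object@d, object@sigmaMin, object@sigmaMax))
})

setMethod("show", "LogisticFit", function(object) {
  cat(sprintf("LogisticFit (%s sigmoid): %d iterations, |grad| = %.3g%s\n",
              object@sigmoidMode, object@iterationsRun, object@gradNorm,
              if (object@converged) " (converged)" else ""))
  print(object@beta)
})

setMethod("show", "SnpStats", function(object) {
  m <- length(object@numerator)
  cat(sprintf("SnpStats: %d SNPs (%d masked)%s\n", m, sum(object@masked),
              if (length(object@logStat) > 0) ", with log-domain stat" else ""))
  if (m > 0) {
    ord <- order(object@pvalue)
    print(utils::head(as.data.frame(object)[ord, ], 5L))
  }
})

setMethod("show", "FixedPointSpec", function(object) {
  cat(sprintf("FixedPointSpec: scale %.6g, %d fractional bits, budget %g, policy '%s'\n",
              object@scale, object@fracBits, object@torusBudget,
              object@overflowPolicy))
})

setMethod("show", "PolyApprox", function(object) {
  cat(sprintf("PolyApprox: degree %d%s on [%g, %g], max fit error %.3g\n",
              object@degree, if (object@even) " (even)" else "",
              object@fitLo, object@fitHi, object@maxError))
})
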