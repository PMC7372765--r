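#' Generate a synthetic genotype/phenotype dataset
#'
#' Emulates the statistical structure the pipeline assumes: an intercept
#' plus `k` standard-normal covariate columns, independent Bernoulli(MAF)
#' binary genotypes, and a logistic outcome `y_i ~ Bernoulli(sigmoid(x_i'
#' betaCov + sum_causal gamma * S_causal))`. Covariate distributions are a
#' modeling choice (standard normal); the default intercept sets the
#' baseline prevalence near 0.45. Fully determined by `seed`.
#'
#' @param n,m,k sample count, SNP count, covariate count (excluding the
#'   intercept).
#' @param maf per-SNP minor-allele frequency vector in `(0, 0.5]`, a
#'   length-2 range to sample uniformly from, or a scalar; default samples
#'   `[0.05, 0.5]`. A zero MAF is allowed only with `allowMonomorphic =
#'   TRUE` (test mode) and yields a monomorphic column that downstream
#'   code flags as masked.
#' @param betaCov true effects, length k+1 including intercept; default
#'   `c(qlogis(0.45), rep(0.5, k))`.
#' @param causal list of `c(index, effect)` pairs (or a 2-column matrix)
#'   adding SNP effects to the linear predictor; default none (null SNPs).
#' @param seed integer seed; every draw flows from it.
#' @param allowMonomorphic permit `maf = 0` entries.
#' @return A [GwasDataset-class].
#' @examples
#' d <- generateDataset(n = 100, m = 20, k = 3, seed = 1)
#' table(phenotype(d))
#' @export
generateDataset <- function(n, m, k, maf = c(0.05, 0.5), betaCov = NULL,
                            causal = NULL, seed = 1L,
                            allowMonomorphic = FALSE) {
  stopifnot(n >= k + 2, m >= 1, k >= 0)
  if (is.null(betaCov)) betaCov <- c(qlogis(0.45), rep(0.5, k))
  if (length(betaCov) != k + 1)
    stop("betaCov must have length k + 1 (intercept first)")
  set.seed(as.integer(seed))
  mafVec <- if (length(maf) == 1L) rep(maf, m)
            else if (length(maf) == 2L && m != 2L) runif(m, maf[1], maf[2])
            else maf
  if (length(mafVec) != m) stop("maf must be a scalar, range, or length-m vector")
  lo <- if (allowMonomorphic) 0 else .Machine$double.eps
  if (any(mafVec < lo | mafVec > 0.5))
    stop("maf entries must lie in (0, 0.5]")
  X <- cbind(`(Intercept)` = 1,
             matrix(rnorm(n * k), n, k,
                    dimnames = list(NULL, if (k > 0) paste0("cov", 1:k))))
  S <- matrix(rbinom(n * m, 1L, rep(mafVec, each = n)), n, m)
  storage.mode(S) <- "double"
  colnames(S) <- paste0("snp", seq_len(m))
  eta <- drop(X %*% betaCov)
  if (!is.null(causal)) {
    cm <- if (is.matrix(causal)) causal else do.call(rbind, causal)
    if (any(cm[, 1] < 1 | cm[, 1] > m)) stop("causal SNP index out of range")
    for (r in seq_len(nrow(cm)))
      eta <- eta + cm[r, 2] * S[, cm[r, 1]]
  }
  y <- rbinom(n, 1L, plogis(eta))
  GwasDataset(X, y, S)
}

#' Dataset shaped like the iDASH 2018 benchmark
#'
#' `n = 245` patients, `m = 10643` binary SNPs, `k = 3` covariates, MAF
#' sampled uniformly in `[0.05, 0.5]` (the lower bound avoids monomorphic
#' columns at this sample size), and no causal SNPs by default — the
#' dimensions of the competition dataset the pipeline was designed around.
#'
#' @param seed integer seed.
#' @param causal optional causal specification as in [generateDataset()].
#' @return A [GwasDataset-class] with dimensions 245 x 4 (X), 245 (y),
#'   245 x 10643 (S).
#' @export
idashLike <- function(seed = 1L, causal = NULL) {
  generateDataset(n = 245, m = 10643, k = 3, maf = c(0.05, 0.5),
                  causal = causal, seed = seed)
}
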