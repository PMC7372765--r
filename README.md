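# sparGWAS

Semi-parallel logistic-regression GWAS with encryption-friendly
numerics, in plaintext R.

## What it does, and for whom

Genome-wide association studies test each of m SNPs for association
with a binary phenotype after adjusting for clinical covariates.
Refitting a logistic regression per SNP is slow and — in
privacy-preserving settings evaluated under homomorphic encryption —
infeasible. `sparGWAS` implements the semi-parallel alternative: fit the
covariate-only model

σ(u) = 1 / (1 + e^(−u)),  Pr(yᵢ = 1) = σ(xᵢᵀβ),

once by gradient descent, then score **all** SNPs jointly. With fitted
probabilities p, weights wᵢ = pᵢ(1 − pᵢ), Gram matrix G = XᵀWX and
cross-product A = XᵀWS, the Wald-type statistic for SNP j is

t_j = (y − p)ᵀS_j / √(s*²_j),  s*²_j = Σᵢ wᵢ S²ᵢⱼ − A_jᵀ G⁻¹ A_j,

and p_j = 2(1 − Φ(|t_j|)). The numerator identity holds because the
gradient Xᵀ(y − p) vanishes at convergence; an explicit
projection-based oracle (`oracleSemiparallel()`) verifies it in the
test suite.

Around this core the package carries, in testable plaintext form, the
numeric machinery an encrypted evaluation needs:

* gradient descent with an exact or lookup-table-discretized sigmoid
  (`buildSigmoidLUT()`, the blind-rotate analog);
* Taylor-series and Cholesky Gram inversion (`invertGTaylor()`,
  `invertGExact()`), with `orthonormalizeDesign()` to reach the
  G ≈ I/4 regime where the series converges;
* fixed-point torus scaling: range simulation (`simulateRanges()`),
  scale derivation (`deriveScale()`, e.g. [−4, 4] → 1/16), quantized
  pipeline execution (`runQuantized()`) and overflow checks
  (`checkOverflow()`);
* a log-domain statistic log|t| = log|num| − log(s*²)/2 via a degree-8
  even least-squares polynomial approximation of a smoothed
  log-absolute-value (`smoothedLogabs()`, `fitLogabsPoly()`,
  `logDomainStat()`);
* a synthetic genotype/phenotype generator (`generateDataset()`,
  `idashLike()`) and CSV/TSV/VCF ingestion (`readInputs()`).

It is aimed at method developers studying the numerical behavior of
encryption-friendly GWAS pipelines, and at anyone who needs a fast,
validated semi-parallel score scan on binary genotypes.

## Worked example

```r
library(sparGWAS)

d <- generateDataset(n = 500, m = 200, k = 3, seed = 42,
                     causal = list(c(7, 1.2)))
d
#> GwasDataset: 200 SNPs x 500 samples, 3 covariates (+ intercept), binary genotypes
#>   cases: 282 / 500

fit <- fitLogisticGD(d, fitConfig(iters = 2e5, tol = 1e-10))
fit
#> LogisticFit (exact sigmoid): 32 iterations, |grad| = 6.21e-11 (converged)
#> (Intercept)        cov1        cov2        cov3
#>   0.3283760   0.4028157   0.4426329   0.4593593

res <- snpAssociation(d, fitConfig(iters = 2e5, tol = 1e-10))
res
#> SnpStats: 200 SNPs (0 masked)
#>        snp_id  numerator denominator     tstat       pvalue masked
#> snp7     snp7  27.777688   25.452688  5.505912 3.672618e-08      0
#> snp35   snp35   8.004607    7.117956  3.000284 2.697280e-03      0
#> snp63   snp63 -15.080604   25.331083 -2.996345 2.732368e-03      0
#> snp163 snp163  12.998198   24.135949  2.645763 8.150687e-03      0
#> snp23   snp23 -13.224146   27.375523 -2.527472 1.148869e-02      0
```

The planted causal SNP (index 7, effect 1.2 on the log-odds scale)
tops the ranking at p ≈ 3.7e-8; the 199 null SNPs behave like draws
from a uniform p-value distribution. `numerator` is the
residual-genotype inner product (y − p)ᵀS_j, `denominator` the squared
residual norm s*²_j of the weighted genotype column, and `tstat` their
ratio — asymptotically standard normal for a null SNP. Monomorphic
SNPs would appear with `masked = 1` and `NaN` statistics rather than
being dropped.

The fixed-point layer reports the ranges that drive the torus scales:

```r
simulateRanges(d, fitConfig(iters = 2e5, tol = 1e-10))
#>   variable        avg    stdev        min      max
#> 1        p  0.5640000  0.16245  1.301e-01   0.9113
#> 2        W  0.2195663  0.03457  8.079e-02   0.2500
#> 3       z* -0.0610158  5.19360 -1.508e+01  27.7777
#> ...
```

A command-line surface with `simulate`, `fit`, `stats`, `ranges` and
`compare-quantized` subcommands is installed at
`system.file("cli", "spargwas.R", package = "sparGWAS")`.

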