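---
title: "Semi-parallel logistic GWAS with encryption-friendly numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-parallel logistic GWAS with encryption-friendly numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparGWAS)
```

## The statistical problem

A genome-wide association study asks, for each of m SNPs, whether the
variant is associated with a binary phenotype after adjusting for k
clinical covariates. The textbook answer fits m separate logistic
regressions `y ~ X + S_j` and reports the Wald z-statistic of the SNP
coefficient. The semi-parallel approach fits the covariate-only model

\[
\Pr(y_i = 1) = \sigma(x_i^\top \beta), \qquad \sigma(u) = \frac{1}{1+e^{-u}},
\]

**once**, and then scores all m SNPs jointly with linear algebra. Writing
`p` for the fitted probabilities, `W = diag(w)` with `w_i = p_i(1-p_i)`
(the logistic variance function), and the IRLS working response
`z_i = x_i^\top\beta + (y_i - p_i)/w_i`, the one-step score statistic for
SNP j is

\[
t_j \;=\; \frac{z^{*\top} W S^*_j}{\sqrt{s^{*2}_j}},
\]

where the asterisks denote residualization against the covariate span in
the `sqrt(W)` geometry. The package's central identity is that, *at the
maximum-likelihood point*, the gradient `X^\top (y - p)` vanishes, so the
numerator collapses to the residual-genotype inner product and the
denominator to two precomputable Gram forms:

\[
\text{numerator}_j = (y - p)^\top S_j, \qquad
s^{*2}_j = \sum_i w_i S_{ij}^2 - A_j^\top G^{-1} A_j,
\]

with `G = X^\top W X` ((k+1) x (k+1)) and `A = X^\top W S` ((k+1) x m).
For binary genotypes the element-wise square `S*S` equals `S`, saving one
pass. `snpAssociation()` implements this path; `oracleSemiparallel()`
implements the unsimplified projection form (explicit orthogonal
projector onto the span of `sqrt(W) X`) and is used throughout the test
suite as the independent reference. The identity is exact only at
convergence: the tests verify that the discrepancy between the two paths
shrinks monotonically as the gradient tolerance tightens from 1e-2 to
1e-10.

Two-sided normal p-values `2(1 - \Phi(|t|))` are attached because the
one-step score statistic is asymptotically standard normal under the
null; this matches the usual GWAS Wald convention. The reference
distribution is a package decision — the statistic itself is the primary
output, and any monotone transform of `|t|` carries the same information.

## Why the numerics look the way they do

The pipeline mirrors an evaluation under torus-based homomorphic
encryption, where only additions, scalar products and table lookups are
cheap, division is essentially unavailable, and every plaintext must be
embedded into the torus (reals mod 1) by a fixed scale factor. The
package keeps all of that machinery, in plaintext, so its behavior can be
measured:

* **Gradient descent instead of IRLS.** Newton/IRLS needs a matrix
  inverse per iteration; plain gradient ascent
  `beta <- beta + alpha X^\top (y - \sigma(X\beta))` needs none. The
  default step `alpha = 4 / ||X||_2^2` is the Lipschitz bound of the
  logistic gradient, which guarantees monotone ascent of the
  log-likelihood (tested). The default schedule is a fixed 30 iterations
  with no convergence test (`fitConfig(iters = 30, tol = 0)`), mirroring
  a fixed-depth encrypted circuit; setting `tol > 0` enables early
  stopping, used when the oracle identity requires tight convergence.
  Initialization is `beta0 = alpha X^\top (y - 1/2)`, i.e. one update
  from zero using `sigma(0) = 1/2`.
* **Lookup-table sigmoid.** Encrypted function evaluation tabulates the
  sigmoid on `d+1` uniform nodes over `[sigma_min, sigma_max]`
  (`buildSigmoidLUT()`); an encrypted argument selects the nearest node.
  The plaintext analog rounds `(x - sigma_min)/(sigma_max - sigma_min) * d`
  half-to-even and clamps to `[0, d]` — the quantization rule of the
  encrypted primitive is not observable, so round-half-even was chosen
  for its lack of bias, and clamping reproduces saturation. With the
  default range `[-4, 4]` (the observed linear-predictor range of the
  fitted model, widened for safety) and `d = floor(8192/4) - 1 = 2047`
  levels, the sup-norm error is bounded by half a node step times the
  maximal slope 1/4, about 4.9e-4. The table stores bare sigmoid values;
  the encrypted formulation fuses the step and design entries into the
  table, which is algebraically identical and done here in the update
  instead.
* **Gram inversion.** `G` is tiny ((k+1)^2), so a Cholesky inverse
  (`invertGExact()`) is the accurate route. The alternative,
  `invertGTaylor()`, expands `G^{-1} = 4\sum_t (-\varepsilon)^t` around
  `\varepsilon = 4G - I`, which converges when the spectral radius of
  `\varepsilon` is below 1. That regime is reached by exploiting basis
  invariance: the statistics are unchanged when `X` is replaced by any
  basis of its span, and with an orthonormal basis
  (`orthonormalizeDesign()`) and weights at most 1/4, `G` sits near
  `I/4`. Order 0 then returns `4I`, already a workable inverse for
  well-balanced data. Note the series must be written in terms of
  `\varepsilon = 4G - I`; expanding in `G - I/4` without the factor 4
  per term does not converge to the inverse dimensionally.
* **Log-domain statistic.** Division by `sqrt(s*2)` is replaced by a
  subtraction of logarithms:
  `log|t| = log|num| - log(s*2)/2`. Since a polynomial cannot follow
  `log|x|` into its vertical asymptote, the target is first smoothed
  (`smoothedLogabs()`): `log|x|` outside a threshold `th`, and the
  matched quadratic `a x^2 + b` inside, with `a = 1/(2 th^2)`,
  `b = log(th) - 1/2` — the unique solution making the function
  continuous and differentiable at `x = th`. A degree-8 even
  least-squares polynomial (`fitLogabsPoly()`) approximates it on a
  uniform grid (uniform, not Chebyshev, because plain least squares is
  the stated design; 4096 nodes by default). The numerator sign is kept
  separately and exactly — `log|.|` discards it, but p-values depend
  only on `|t|`, so nothing downstream changes.

### Log-domain parameter defaults

`th = 0.05`; fit ranges `[-35, 35]` for the numerator and `[-15, 15]`
for the denominator. These cover, with a margin, the intermediate ranges
the range simulator reports on benchmark-shaped synthetic data
(numerator roughly ±31, denominator below 15). A degree-8 polynomial
over so wide a range is coarse: its grid max error is a few units,
concentrated near the origin where the smoothed log dips to `b`. The
tests therefore assert the two things that are actually guaranteed —
reconstruction of `|t|` within the combined fit error, and preservation
of the SNP ranking for pairs separated by more than the local residuals
— rather than a fixed small error. The squaring-and-centering variant
(feeding `s*` instead of `s*2`) exists only in the encrypted dataflow,
where the denominator arrives unsquared; the plaintext pipeline already
carries `s*2`, so the default path consumes it directly.

## Fixed-point model

`FixedPointSpec` models one variable's torus embedding: multiply by
`scale`, round to the dyadic grid `2^-f` (round-half-even), then apply
the overflow policy. `wrap` is exact mod-1 reduction into
`[-1/2, 1/2)`; `strict` raises an error naming the variable; `none`
performs pure grid rounding with no torus reduction and exists so that
fidelity studies can isolate rounding error from wraparound (at
`f = 53` and unit scale it reproduces double precision to ~1e-15). Only
a quarter of the torus is usable by default because negacyclic function
evaluation restricts plaintexts to half a period; `deriveScale(min, max,
budget)` maps the widest observed magnitude onto that budget — for the
linear predictor range `[-4, 4]` this yields the scale 1/16.

`simulateRanges()` runs the exact pipeline once and reports
avg/stdev/min/max for the eight tracked intermediates (`p`, `W`, `z*`,
`G`, `A`, `s*2`, `r_i`, `p-value`); `twoPassSpecs()` turns that report
into per-variable scales — the same plaintext-simulation route the
encrypted implementation used to pick its scales — and
`checkOverflow()` flags any variable whose observed peak escapes its
budget. `runQuantized()` then executes the scan with the LUT sigmoid in
the regression and a quantize/dequantize round trip after each named
intermediate. Quantization is applied at that granularity — after each
ciphertext-shaped object, never inside a BLAS accumulation — because
that is where an encrypted evaluation rounds. At 20 fractional bits with
two-pass scales the quantized and exact statistic vectors correlate
above 0.999999 on benchmark-shaped data; the deviation is non-increasing
in `f` (tested over f = 8, 12, 16, 20, 24).

## The synthetic generator

`generateDataset()` emulates the structure the pipeline assumes:
standard-normal covariates behind an intercept, independent
Bernoulli(MAF) binary genotypes (presence coding, not diploid dosages),
and logistic outcomes driven by the covariates plus declared causal SNP
effects. The intercept default `qlogis(0.45)` puts the baseline
prevalence near 0.45, and covariate effects default to 0.5 — moderate,
realistic confounding. `idashLike()` fixes the benchmark shape
n = 245, m = 10643, k = 3 with MAF uniform on [0.05, 0.5]; the lower
bound keeps columns polymorphic at that sample size. The generator does
**not** model linkage disequilibrium, population stratification or
Hardy-Weinberg genotypes, so passing tests demonstrate correctness of
the algebra and calibration under independence — not robustness to
confounded real cohorts.

Monomorphic columns (possible only via the explicit
`allowMonomorphic = TRUE` test mode, or in real data) have a zero
denominator; they are flagged in the output (`masked = 1`, `NaN`
statistics) rather than dropped, with threshold `1e-12 * n`.

## Problem sizes and determinism

The test suite and the acceptance script run on synthetic data at
n = 245–1000, m = 400–2000 — large enough for the asymptotics to hold
(null p-value calibration is tested within the 3-sigma binomial band at
m = 2000; a causal SNP of effect 1.0 at n = 1000 is ranked below the
median null p-value in 100/100 replicates), small enough to iterate
comfortably. Every random draw flows from a single integer seed; the
same seed reproduces every matrix bit-for-bit, and the writers emit
byte-identical files on identical inputs.

## Known limitations

* The numerator identity holds at convergence; with the fixed 30-step
  encrypted-style schedule the statistic is a controlled approximation
  whose error is governed by the residual gradient norm.
* The degree-8 log polynomial is coarse near zero; extremely small
  |numerator| or denominator values reconstruct poorly (by design the
  affected SNPs are the least significant ones).
* No LD, relatedness or stratification modeling — real-cohort use needs
  upstream QC as in any score-test pipeline.
* The fixed-point layer models deterministic rounding, not ciphertext
  noise growth; it measures quantization sensitivity, not cryptographic
  behavior.
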