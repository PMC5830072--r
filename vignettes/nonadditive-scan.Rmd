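---
title: "Two-step mixed-model scans for non-additive genetic effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step mixed-model scans for non-additive genetic effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nonaddscan)
```

## The problem

Most genome-wide association scans test the additive dose–response of an
allele: the expected phenotype changes linearly with the number of B-allele
copies. Loci acting through dominance (one copy is as good as two),
recessivity (only the homozygote deviates) or overdominance (the
heterozygote deviates from both homozygotes) are poorly captured by that
single contrast, yet theory predicts exactly such non-additive action for
fitness-related traits — fertility above all. `nonaddscan` implements a
complete scan for these effects in populations of related individuals, the
typical situation in livestock genetics where the motivating application
(dairy-bull conception rate) lives.

Each mode of action is reduced to a single numeric coding of the genotype,
so testing it is a single-degree-of-freedom regression:

* additive: AA = 0, AB = 1, BB = 2
* dominance: AA = 0, AB = 1, BB = 1
* recessive: AA = 0, AB = 0, BB = 1
* overdominance: AA = 0, AB = 1, BB = 0

Two useful identities follow and are enforced by tests: the additive coding
is the identity on dosages, and elementwise
`dominance − recessive = overdominance`.

## The model and the two-step approximation

Relatedness is modelled with the animal model

$$\mathbf{y} = \mathbf{X}\boldsymbol\beta + \mathbf{Z}\mathbf{u} +
\mathbf{e}, \qquad \mathbf{u} \sim N(0, \mathbf{G}\sigma^2_u), \qquad
\mathbf{e} \sim N(0, \mathbf{I}\sigma^2_e),$$

with `G` the genomic relationship matrix. Because each individual carries
exactly one (pre-adjusted) record, the incidence matrix of the animal
effect is the identity; record weights are deliberately not supported (the
residual covariance is a plain identity). Fixed effects default to an
intercept only — the motivating phenotype is already adjusted for
management and mate effects by the national evaluation that produces it —
but a covariate matrix is accepted.

A per-marker mixed-model refit across tens of thousands of markers is
computationally wasteful, so the scan is split:

1. **Step 1** fits the null model (no marker) by REML, yielding variance
   components and the frozen null covariance
   $\mathbf{V}_0 = \mathbf{G}\hat\sigma^2_u + \mathbf{I}\hat\sigma^2_e$.
2. **Step 2** tests each coded marker vector $\mathbf{x}$ with the score
   statistic
   $$z = \frac{\mathbf{x}'\mathbf{V}_0^{-1}(\mathbf{y} -
   \mathbf{X}\hat{\boldsymbol\beta})}
   {\sqrt{\mathbf{x}'\mathbf{V}_0^{-1}\mathbf{x}}},$$
   treated as standard normal; $\hat\beta_{SNP} =
   \mathbf{x}'\mathbf{V}_0^{-1}\mathbf{r} /
   (\mathbf{x}'\mathbf{V}_0^{-1}\mathbf{x})$ and $se =
   (\mathbf{x}'\mathbf{V}_0^{-1}\mathbf{x})^{-1/2}$, so $z = \hat\beta/se$.

Design choices in step 2, where the formulation was genuinely open:

* **Centring.** Each coded vector is mean-centred before testing so the
  step-1 intercept absorbs the coding's baseline; without centring the
  statistic would confound the coding's mean with the trait mean. Two-sided
  p-values are used (estimated effects are signed).
* **No nuisance refit.** $\hat{\boldsymbol\beta}$ and $\mathbf{V}_0$ stay
  frozen from step 1 — the pure two-step form. The statistic therefore
  *approximates* the joint-fit Wald test: both share the numerator
  $\mathbf{x}'\mathbf{M}\mathbf{y}$, but the two-step denominator uses
  $\mathbf{x}'\mathbf{V}_0^{-1}\mathbf{x}$ rather than the (slightly
  smaller) projected form, a conservative difference of order the
  $\mathbf{V}_0^{-1}$-correlation between marker and fixed effects. The
  test suite asserts exact agreement (1e−6) with the two-step formula
  evaluated by dense inversion, and close agreement (2%) with the joint
  Wald statistic.
* **Untestable markers.** A marker whose coding is (numerically) constant —
  e.g. the recessive coding of a marker with no BB individuals — is
  reported with missing statistics and an `untestable` flag, never as
  `z = 0`: a genuine test requires representation of the contrasted class.
* The additive model is always co-computed alongside any requested
  non-additive coding, so every reported marker carries both a
  non-additive and an additive p-value; purely non-additive action shows
  as a significant non-additive p with a negligible additive one.

## REML: algorithm and numerical choices

With `Z = I` the null covariance has the single-parameter form
$\sigma^2 [h^2 \mathbf{G} + (1 - h^2)\mathbf{I}]$, where
$h^2 = \sigma^2_u/(\sigma^2_u + \sigma^2_e)$ and $\sigma^2$ is the total
variance. On the eigenbasis of `G` every restricted-likelihood evaluation
is O(n) after one O(n³) decomposition, and $\sigma^2$ profiles out
analytically. The optimiser is deliberately simple and globally robust: a
grid scan of $h^2$ over [0, 0.99] at step 0.01 followed by golden-section
refinement of the best cell to $|\Delta h^2| < 10^{-6}$ (cap 200
iterations). This avoids the implementation risk of
average-information updates while being trivially checkable against a
dense-matrix oracle; the suite requires 1e−6 agreement of the profiled
restricted log-likelihood with an explicit dense evaluation (the
likelihood constant includes the $-\log|\mathbf{X}'\mathbf{X}|$ term and
the profiled $(n-p)$, so the *value*, not just the argmax, is comparable).
The convergence flag is honest: an optimum on the boundary ($h^2 = 0$ or
$0.99$) reports `converged = FALSE` rather than silently clamping. With an
essentially unrelated sample, $h^2$ is weakly identified and single-fit
estimates scatter widely — the tests therefore assert boundary behaviour
and total-variance recovery there, and reserve point-recovery assertions
for structured (half-sib) samples.

## The genomic relationship matrix

The construction the motivating study left unstated is fixed here as
VanRaden's first method — the standard in dairy genetics:
$\mathbf{G} = \mathbf{W}\mathbf{W}' / (2\sum_j p_j(1-p_j))$ with
$\mathbf{W}$ the column-centred dosage matrix and $p_j$ estimated from the
sample itself (no base-population frequencies exist for synthetic or
repository data). A ridge of 1e−6 on the diagonal guarantees the positive
definiteness that the downstream $\mathbf{V}_0^{-1}$ requires; it is far
below the resolution of any relationship of interest. Missing dosages are
mean-imputed per marker before centring, which leaves column means (hence
allele-frequency estimates) unchanged.

## QC, allele orientation and missing data

Marker editing applies, in order: removal of sex-chromosome markers
(labels X, Y, XY, MT and "30", the bovine X synonym), monomorphic markers,
and markers with minor allele frequency below 1% — computed on observed
calls so that imputation can never rescue a monomorphic marker, with the
boundary convention that MAF exactly 0.01 is retained ("less than 1%" is
removed). Hardy–Weinberg and call-rate filters are intentionally absent.

Text `.ped` files do not define which allele is "B", so the reader adopts
a stable file-defined rule: B is the second distinct allele symbol
encountered per marker. One consequence is worth stating plainly: a
dosage matrix and its orientation flip (d → 2−d with swapped labels)
serialise to byte-identical files, so orientation is recoverable only up
to this rule — one write/read cycle canonicalises a matrix, after which
round trips are bit-exact (and are tested to be). Orientation affects the
labelling of dominance versus recessive findings, not their discovery,
because both codings are scanned.

Missing dosages are mean-imputed on the dosage scale and mapped through
the coding treated as a piecewise-linear function of dosage (dominance
`min(d, 1)`, recessive `max(d − 1, 0)`, overdominance `1 − |d − 1|`).
This preserves coded-column means and keeps the
dominance − recessive = overdominance identity exact even at fractional
imputed values. Genotype-class counts and MAF are always reported from
observed calls only.

## Genomic control and multiple testing

The published analysis corrected inflation with a variance-inflation-style
genomic-control function whose formula is not printed; two standard
estimators that bracket such behaviour are provided. The default is the
classical median estimator $\lambda = \mathrm{median}(z^2)/0.4549$ (the
$\chi^2_1$ median, used at full precision); the alternative regresses
sorted $z^2$ through the origin on expected $\chi^2_1$ order statistics,
trimmed to the lower 90% so true signal in the tail cannot drive the
slope. Exact numerical agreement with the original package is not claimed.
λ is estimated per coding model (each scan has its own null behaviour),
statistics are deflated by $\sqrt\lambda$ only when $\lambda > 1$
(deflation is never "corrected"), and family-wise error is controlled by
Bonferroni at α = 0.01 over the markers actually tested per model.

## The synthetic-data generator

No public data exist for the motivating study (phenotypes from national
evaluations, genotypes from a breed repository), so the generator emulates
the statistical structure the method assumes, and its defaults are the
study conditions used throughout the tests:

* **Family structure**: paternal half-sib families (`n_sires` ×
  `offspring_per_sire`), the natural design for AI bulls. Each sire
  transmits one gamete per offspring; dam alleles come from the population
  frequency (dams unobserved). Expected within-family genomic relationship
  is 0.25, and tests assert the realised GRM shows it. One offspring per
  sire gives an effectively unrelated sample for calibration tests.
* **Markers**: biallelic, allele frequencies uniform on
  [`maf_low`, `maf_high`] (defaults 0.05–0.5), segregating independently —
  no linkage map, no LD blocks. Planted QTLs sit on scanned markers (the
  marker *is* the causal variant), so power tests are self-contained and
  tag-SNP attenuation is out of scope.
* **Phenotype**: `y = μ + Σ effect·code + u + e` with
  `u ~ N(0, G σ²u)` drawn through the eigendecomposition of the realised
  GRM and i.i.d. residuals; μ defaults to 0 because the motivating trait
  is expressed as a deviation from the population mean. Defaults
  σ²u = 0.3, σ²e = 0.7 give the moderate heritability typical of
  male-fertility evaluations.

What passing tests on these data do **not** show: robustness to LD between
markers and causal variants, to multi-generation pedigree structure, to
genotyping error, to phenotype reliabilities varying across bulls, or to
selection — none of which the generator produces.

## Problem sizes and acceptance checks

The statistical acceptance suite uses: 200 half-sib replicates
(n = 500, m = 2,000, true h² = 0.3) for REML recovery (mean ĥ² within
±0.05); 100 null scans of the same size for calibration (empirical type-I
error within [0.04, 0.06] per coding at nominal 0.05, genomic-control λ in
[0.9, 1.1] in ≥ 90% of replicates); 100 replicates at n = 2,000 with a
planted dominance QTL explaining ~1% of variance for the power ordering
(dominance p beats additive p in ≥ 80%); 50 random instances (n ≤ 50) for
dense-oracle equivalence at 1e−6; and exact worked examples whose inputs
are fully published — the genotype-count table of the seven top
non-additive markers (MAF arithmetic to 3 decimals) and the Bonferroni
threshold 0.01/57,838 = 1.7e−07. `scripts/acceptance.R` recomputes the
same quantities at reduced replicate counts (60/40/60) chosen to keep a
fresh run comfortably reproducible; the quantities are stable across seeds
at those sizes.

## Known limitations

* The two-step statistic is slightly conservative relative to an exact
  per-marker mixed-model refit; regions of very strong polygenic signal
  would be better served by exact methods.
* Dominance variance is not modelled in the *null* (step 1 fits a single
  additive genomic component); a marker's non-additive test is conditional
  on that additive background.
* Orientation of "B" is file-defined for text input; analyses of external
  data should re-orient explicitly if allele identity matters for
  interpretation.
* The REML profile is one-dimensional by construction and does not extend
  to multi-component models.
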