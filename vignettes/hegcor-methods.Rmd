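---
title: "Methods: Haseman-Elston genetic correlations and meta-trait mega-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Haseman-Elston genetic correlations and meta-trait mega-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hegcor)
```

# The estimation problem

Diversity Outbred (DO) mice and similar multiparental populations support
fine-grained QTL mapping, but individual studies are small (hundreds of
animals) and phenotype panels differ between labs. `hegcor` implements a
regression-based framework that joins such cohorts: narrow-sense
heritability ($h^2$) and genetic correlations ($r_g$) are estimated from
pairwise statistics only, so two traits never need to be measured on the
same animals — kinship between cohorts is all that is required.

# Haseman-Elston regression

For a z-score-normalized trait $M$, every unordered pair of distinct
individuals $(i, j)$ contributes the product $M_i M_j$ as a phenotypic
similarity score, regressed on the pair's kinship $r_{ij}$:

$$M_i M_j = \alpha + \beta\, r_{ij} + e.$$

Because $M$ has unit variance, the slope converts directly:
$h^2 = \beta / 2$. The factor 2 reflects the kinship convention used
throughout the package: kinship is the probability of sampling the same
allele from the two individuals, i.e. the standardized-genotype
cross-product averaged over markers and divided by two (or, from founder
probabilities, $K_{ij} = \frac{1}{m}\sum_{m,f} P_{imf}P_{jmf}$).

For two traits $M$ and $N$, the same regression on cross products
$M_i N_j$ yields the genetic covariance $\rho_{M,N} = \beta_{M,N}/2$, and

$$r_g = \frac{\rho_{M,N}}{\sqrt{h^2_M\, h^2_N}},$$

estimable whenever both heritabilities are positive (non-positive inputs
return an explicit not-estimable result). When the two cohorts share
animals, each unordered pair contributes the symmetrized response
$(M_iN_j + M_jN_i)/2$ once; pairs spanning cohorts contribute single
products. This keeps the design symmetric in the trait order and avoids
double-counting pairs in the standard error. `he_fit()` evaluates the
regression through closed-form pair sums (no pair enumeration is
materialized), which the test suite verifies against a brute-force
pair-enumeration oracle to $10^{-10}$.

## Standard errors and the correction factor

The raw slope standard error is Fisher's regression formula with
$S_\varepsilon = \sqrt{\mathrm{RSS}/(n_\text{pairs}-2)}$. Pair products
are not independent observations — the effective information shrinks as
$h^2$ and the cohort size grow — so raw SEs become anti-conservative.
The package quantifies this with split-half calibration: simulate a
population, split it into two disjoint halves, estimate $h^2$ in each,
and form

$$\Delta_\text{norm} = \frac{h^2_1 - h^2_2}{\sqrt{\sigma^2_1 + \sigma^2_2}}.$$

Over replicates, the SD of these values ($\sigma_{\Delta\text{norm}}$)
should be $\approx 1$ for well-calibrated SEs. With raw SEs it rises with
$\sqrt{n}$ and $h^2$; the multiplicative repair is

$$F = \sqrt{n}\,(0.020225\,h^2 + 0.004225) + (-0.2352\,h^2 + 0.9467),$$

applied as $SE_\text{corrected} = SE \times F$, with $h^2$ the point
estimate clipped to $[0,1]$ and $n$ the number of *animals* (the
calibration regressions are parameterized by population size, not pair
count). `calibration_experiment()` reruns the whole experiment and
`derive_correction_coefficients()` re-derives the four coefficients by
two-stage least squares ($\sigma_{\Delta\text{norm}} \sim \alpha +
\beta\sqrt{n}$ per $h^2$ level, then the intercepts and slopes regressed
on $h^2$); a noiseless table round-trips the coefficients to $10^{-8}$.

For cross-trait coefficients the calibration parameterization is
ambiguous (which $h^2$, which $n$?); the package evaluates $F$ at the
mean of the two trait heritabilities and the smaller of the two cohort
sizes. This is a package choice, exposed through the `coefficients`
argument so alternatives can be substituted.

## Error propagation for genetic correlations

$SE(r_g)$ propagates the relative variances of the three ingredients:

$$SE(r_g) = |r_g| \sqrt{\left(\tfrac{SE(\rho)}{\rho}\right)^2 +
\left(\tfrac{SE(h^2_M)}{2h^2_M}\right)^2 +
\left(\tfrac{SE(h^2_N)}{2h^2_N}\right)^2},$$

computed in the algebraically equivalent form
$\sqrt{SE(\rho)^2/(h^2_Mh^2_N) + r_g^2(\ldots)}$ so that $\rho = 0$
yields a finite SE rather than $0 \cdot \infty$. The raw relative-variance
sum is returned as `rel_var_sum` for audit. Slope p-values are two-sided
t tests with $n_\text{pairs} - 2$ degrees of freedom; they inherit the
pair non-independence discussed above and should be read accordingly
(the SE correction applies to standard errors, not p-values).

## Filters

Traits are retained when $h^2 \ge 0.10$ and $h^2 \le 1 + SE$; genetic
correlations are valid when $-1 - SE \le r_g \le 1 + SE$. Both rules are
exact rule evaluations (`filter_traits()`, `filter_rg()`) with exclusion
reasons recorded.

# The genetic-correlation atlas

`rg_matrix()` estimates all unordered trait pairs and the phenome-wide
Bonferroni threshold $\alpha / \binom{T}{2}$. The clustering similarity
is not $r_g$ itself but the Pearson correlation of two traits'
z-score-normalized $r_g$ vectors across the whole atlas ($r_{pg}$),
which is far more noise-robust than any single $r_g$. Each trait's
vector is z-scored over its finite, valid off-diagonal entries; for a
pair $(a,b)$ the mutual and self entries are excluded (standard practice
for correlations of correlations) and cells with fewer than three shared
entries are masked.

Since positive and negative correlations both indicate shared genetics,
$|r_{pg}|$ is converted to a distance $d = \sqrt{2n(1-|r_{pg}|)}$ (the
non-negative algebraic form of $\sqrt{-2n(|r_{pg}|-1)}$) and clustered
with Ward-D2 agglomeration.

## Meta-traits and choosing the cluster count

A cluster's meta-trait is the per-individual mean of its sign-aligned,
z-scored members, re-z-scored (re-normalization keeps the $h^2 = \beta/2$
identity applicable). The focal member is the trait with the highest
$h^2$; members with negative $r_{pg}$ against it are sign-flipped.
Individuals with no member measurement are missing.

The cluster count $k$ is chosen by cutting the dendrogram at each
candidate $k$, computing per cluster the heritability ratio

$$h^2_\text{ratio} = \frac{h^2_\text{meta}}{0.5\,(h^2_\text{sub1} + h^2_\text{sub2})}$$

over its two child sub-dendrograms, and averaging across clusters;
`sweep_k()` returns the maximizing $k$ (smallest on ties — coarser
clustering means fewer downstream scans). Singleton clusters have no
children and are excluded from the mean, as are ratios with non-positive
denominators.

A caveat worth stating plainly: on synthetic atlases built from blocks
with *uniform* within-block correlation and independent noise, the mean
ratio does not peak at the block count. Meta-trait heritability is a
concave increasing function of the number of averaged members, so the
per-merge gain — which is what the ratio measures — is always largest
for pair merges; the curve keeps rising past the block count toward the
all-pairs cut, even though cutting at the block count recovers the
planted blocks exactly (a property the test suite verifies). Interior
optima of the kind seen in heterogeneous real atlases arise when many
fine-scale merges join traits measured on disjoint animals (averaging
then cannot cancel noise) or with unequal within-cluster correlation;
uniform synthetic blocks have neither feature. The package therefore
treats the sweep's curve, not only its argmax, as the informative output.

## Intra-trait correlations across groups

`group_rg_summary()` estimates a trait's $r_g$ between measurement
groups (time points, diets) as cross-cohort HE regressions on disjoint
animal sets, drops estimates outside the validity band, and reports the
mean and standard error per group pair across traits.

# Genome scans of meta-traits

`genome_scan()` performs fixed-effect Haley-Knott regression of the
meta-trait on founder-haplotype probabilities plus an intercept at each
pseudomarker, with $\mathrm{LOD} = (n/2)\log_{10}(\mathrm{RSS}_0 /
\mathrm{RSS}_1)$. The founder columns sum to one; a rank-revealing QR
handles the collinearity, and the LOD is invariant to the choice of
generalized inverse. No additive covariates are used — the phenotype
workflow has already absorbed age, sex, generation and diet. A
kinship-rotation variant (eigendecomposition of $2K$ with a null-model
ML variance ratio) is available behind the `kinship` argument for parity
checks; on unlinked synthetic markers the correction is second-order,
and the fixed-effect scan is the package's reference method because it
is exactly testable against a two-model OLS oracle.

Significance uses unrestricted permutations: meta-trait values are
shuffled across individuals, the genome rescanned, and the 95th
percentile of the maximum-LOD distribution taken as the $\alpha = 0.05$
threshold (1,000 permutations by default). Scans of many phenotype
columns share one pass over the markers, so permutations cost one matrix
product per marker rather than one scan each.

Peaks are local maxima above the threshold; two maxima are distinct
only when the profile between them dips by at least `peakdrop = 3` below
the lower of the two, and each peak carries the widest contiguous span
with LOD within `drop = 2` of the peak (the 2-LOD support interval),
truncated at chromosome ends. The per-QTL variance explained is
$1 - 10^{-(2/n)\mathrm{LOD}}$.

Permutation FDR counts, at each LOD threshold, peaks in permuted scans
as false discoveries and observed peaks as true ones:
$\mathrm{FDR}(t) = \mathrm{mean}_p\,[F_p / (F_p + T)]$ with $0/0 = 0$.
The reported curve is made monotone non-increasing by a running maximum
over decreasing thresholds (raw values retained). Both conventions of
the expected-count summary are reported with explicit labels —
`expected_false` $= \mathrm{FDR}\cdot T$ and `expected_true`
$= (1-\mathrm{FDR})\cdot T$ — because the two are easily conflated.

Founder-allele effects at a sentinel marker are shrunken (BLUP-style)
estimates: a single variance component, strength chosen by maximizing
the single-locus marginal likelihood over the variance ratio on a log
grid. Centering the design columns makes the effects sum to zero
exactly; standard errors come from the conditional posterior, and the
unshrunken minimum-norm least-squares counterparts are returned
alongside. `effect_correlation()` compares two loci's effect vectors by
Pearson correlation with $f - 2$ degrees of freedom.

# The synthetic cohort generator

The generator reproduces the statistical structure of the package's
calibration experiments:

* genotypes: 1,000 unlinked biallelic markers per cohort, dosages drawn
  binomially at frequencies sampled from $\{0.05, 0.1, 0.3, 0.4\}$;
* traits: 10 causal markers with independent normal effects on
  standardized dosages; standardization uses the *seeded* allele
  frequency (deterministic), while kinship standardizes by the
  *empirical* frequency of the analyzed cohort;
* noise: scaled against the realized variance of the genetic values so
  every simulated cohort attains its target $h^2$ closely — calibrating
  against the theoretical variance would let the realized $h^2$ drift by
  the sampling error of the causal effects, loosening every recovery
  test at no benefit;
* pleiotropy: trait pairs (and blocks) share one causal set with
  effect sizes drawn from a bivariate (or shared-plus-independent)
  normal at the target correlation — a deliberate extension of the
  single-trait design, since cross-trait recovery needs a ground truth;
* founder probabilities: two founder alleles drawn uniformly per
  individual and marker, giving valid 8-state probability vectors.

What the generator deliberately does **not** emulate: linkage
disequilibrium, realistic DO pedigree structure and its kinship
gradients, genotyping-array error modes, or non-Gaussian trait
distributions. Passing tests therefore demonstrate correctness of the
estimators under their own assumptions and the calibration of the SE
machinery — not robustness to LD or population structure.

# Numerical and design choices

* **Pair bookkeeping.** Self-pairs are never used; overlapping-cohort
  pairs are symmetrized and counted once.
* **Missing data.** Pairs containing a missing phenotype are dropped
  before the regression; individuals lacking covariates become missing
  for that trait; meta-trait values exist wherever at least one member
  is measured.
* **z-scoring** uses the sample (n−1) SD throughout, applied within the
  analyzed stratum.
* **Outliers** (beyond 5 SD of the trait mean) are excluded in a single
  pass before model fitting; the order matters and is tested with an
  outlier that would otherwise flip a covariate coefficient's sign.
* **Interpolation** of founder probabilities is per-founder linear in
  physical position with end clamping, then renormalized — the simplest
  rule that preserves the probability simplex.
* **Monomorphic markers** are dropped from genotype kinship with a
  warning; an all-monomorphic input is an error.
* **Degenerate regressions** (fewer than 3 pairs, zero kinship
  variance) are errors, not NaNs; non-positive heritabilities make
  $r_g$ explicitly not-estimable.
* **Tie-breaks**: `sweep_k()` picks the smallest maximizing $k$;
  `find_peaks()` orders candidate maxima by LOD so the taller of two
  merged maxima names the peak.
* **X chromosome** is treated like an autosome.
* **Problem sizes in the shipped tests** were chosen to keep the suite
  fast while leaving the statistical checks sharp: split-half
  calibration uses 500 replicates at $n = 1000$ per half (and 30
  replicates at $n = 5000$ for the raw-SE miscalibration direction,
  where the effect size is large), recovery experiments 200 replicates
  per condition, and scan calibration 200 permutations in 100 null
  replicates.

# Reproducibility

Every stochastic function takes a `seed`; `run_pipeline()` derives all
stage seeds from a single root seed, records parameters and input/output
checksums in `manifest.json`, resumes completed stages by checksum, and
reproduces outputs byte-for-byte on rerun.

# Known limitations

* HE regression is less efficient than REML at equal sample size; its
  appeal here is closed-form speed across millions of trait pairs and
  its indifference to cohort overlap.
* The response construction carries a small finite-sample bias: the
  trait is z-scored by its sample variance, which correlates with the
  pair products it normalizes, depressing the slope by a term of order
  $1/n$ (fractions of a percent at cohorts of hundreds). The effect is
  inherent to product-based HE with sample standardization — it persists
  when the regressor is replaced by the true causal-sharing matrix — and
  is negligible relative to the estimator's sampling SD at any single
  cohort size, but it is resolvable in very large replicate averages.
* P-values from pair regressions are anti-conservative; only SEs are
  corrected by $F$. Threshold-based filtering downstream should use the
  corrected SEs.
* The fixed-effect scan does not model polygenic background; for
  strongly structured cohorts the kinship-rotation variant (or an
  external mixed-model scanner) is preferable.
* The $F$ coefficients were derived under the generator's simulation
  design; cohorts with very different relatedness spectra may need
  re-derivation via `calibration_experiment()` +
  `derive_correction_coefficients()`.
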