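---
title: "Inversion-aware association mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inversion-aware association mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invgwas)
```

## The problem

Cosmopolitan chromosomal inversions — In(2L)t, In(3R)Mo and their kin in
*Drosophila melanogaster* — segregate at intermediate frequency and suppress
recombination in heterozygotes. In a panel of inbred lines this has two
consequences that pull in opposite directions for association mapping:

1. the inversion itself behaves like a single large-effect, high-frequency
   variant, and can account for an appreciable share of line-mean trait
   variance; and
2. the long block of variants in linkage with the inversion dominates
   genome-wide estimates of relatedness, so mixed-model associations that
   correct for relatedness with a full-genome GRM absorb exactly the signal
   one is trying to detect ("proximal contamination").

`invgwas` implements the full analysis chain for studying both effects on a
panel of homozygous lines, together with a synthetic panel generator so that
every stage is testable without external genotype or phenotype downloads.

## Models

### Inversion-trait models and the matched-frequency null

For each trait and inversion, `inversion_trait_lm()` fits ordinary least
squares of the line means on an INV indicator using homozygous (INV or STD)
lines only. Heterozygous calls are excluded: in an inbred line a
"heterozygous" karyotype call means the inverted-allele content of the line
is unknown, not 50%. The model is compared to the intercept-only null with
an F test on (1, n − 2) degrees of freedom; for a binary predictor the model
R² is the squared point-biserial correlation, which the test suite verifies
as an identity.

A significant fit alone does not show that the *inversion* is special — any
variant of comparable frequency might explain as much. `matched_null()`
therefore refits the model on variants sampled from the same chromosome arm,
matched to the inversion's allele frequency within ±1% (the tolerance is a
parameter, `freq_tol`), lying outside the inversion body and more than 2 Mb
from both breakpoints, where tagging LD has decayed. A trait is flagged
*inversion-associated* only when the observed model is significant at
p < 0.05 **and** its R² strictly exceeds the 95th order statistic of the
matched-variant R² distribution.

Two definitions of the inversion "frequency" used for matching are
available, because the choice is genuinely open: allele frequency counting
heterozygous calls, f = (2·nINV + nHET)/(2·n) (the default), or the
proportion of INV homozygotes. At the default heterozygote fraction of zero
the two coincide.

### Relatedness

Three GRM recipes are implemented:

* **Full** (`grm_vanraden()`): VanRaden's K = ZZ′ / (2Σpⱼ(1−pⱼ)) on all
  variants with MAF > 0.05 and missing rate < 0.20; missing dosages are
  mean-imputed before centering.
* **LD** (`grm_gcta()` after `ld_prune()`): the GCTA estimator — per-variant
  standardized dosages averaged with pairwise exclusion of missing entries —
  on variants with MAF > 0.05, missing rate < 0.15, thinned so that no
  retained pair within 5 kb has r² > 0.2. Pruning is greedy left-to-right
  within each arm with earlier-position-wins tie-breaking, which makes the
  retained set deterministic.
* **LOCO** (`grm_loco()`): the LD recipe restricted to all arms except the
  one being scored, so the scored arm (and any inversion on it) cannot
  contaminate its own relatedness correction.

All thresholds are strict inequalities; boundary values are excluded. Note
one numerical consequence of pairwise exclusion: with appreciable
missingness and modest variant counts the GCTA-style matrix is mildly
indefinite. `grm_eigen()` clamps ("bends") negative eigenvalues within 25%
of the mean diagonal to zero — standard mixed-model practice — and raises an
error beyond that. On complete-genotype panels all three recipes are
positive semidefinite to 1e−8, which the test suite asserts.

For fully inbred panels the dosage variance at a variant is 4p(1−p) rather
than the Hardy–Weinberg 2p(1−p), so VanRaden diagonals sit near 2, not 1.
This is expected and does not affect any downstream test, which are all
invariant to a global scaling of K.

### The mixed model and score test

`fit_null_lmm()` fits y = Xβ + b + ε with b ~ N(0, τ_g K), ε ~ N(0, τ_e I),
by exact restricted maximum likelihood: K is eigendecomposed once, the
restricted likelihood is profiled over the variance ratio h = τ_g/τ_e
(diagonal algebra in the eigenbasis), and the 1-D profile is maximized by a
41-point grid scan refined with Brent optimization. The boundary h = 0 is
always evaluated and permitted. This is deterministic and exact for one
random effect; no iterative REML with convergence tuning is involved. The
fixed effects are an intercept plus *Wolbachia* infection status (0/1).

`score_test()` computes, for each variant dosage vector g (MAF ≥ 0.05,
missing ≤ 0.15 on the included lines, missing dosages mean-imputed),

> T = (g′Py)² / (g′Pg),   P = V⁻¹ − V⁻¹X(X′V⁻¹X)⁻¹X′V⁻¹,

χ²₁-distributed under the null, plus the effect approximation β̃ = g′Py/g′Pg
and se = (g′Pg)^(−1/2) used later for colocalization. At K = I the statistic
reduces to the classical OLS score test, and its p-values track the OLS
t-test p-values with correlation above 0.999 on null panels of 200 lines —
both verified in the acceptance suite.

`run_gwa()` wires the four strategies: **full** (VanRaden GRM), **ld** (GCTA
GRM), **factored_out** (VanRaden GRM on the residuals of trait ~ inversion
karyotypes, each inversion a categorical factor; `factored_out_residuals()`),
and **loco** (per arm, refit the null model with that arm's exclusion GRM and
score only that arm's variants). Permutations shuffle the trait vector
across lines — covariates and the GRM stay attached to their lines — and the
null model is refit for every replicate. Heterozygous-karyotype lines are
retained in the GWA stage (the scan makes no distinction between inverted
and non-inverted regions or lines), unlike the homozygote-only inversion
linear models.

### Calibration of the permuted null, and one caveat

Under a permuted trait the score-test p-values of variants whose structure
the GRM does not absorb are uniform; the acceptance suite checks this with
Kolmogorov–Smirnov tests across 50 permutation replicates. Inversion-tagged
variants under a *full-genome* GRM are a different matter: the GRM absorbs
the karyotype direction, and their null p-values are conservatively
*deflated* (we verify they are never anticonservative). This deflation is
not a defect of the test — it is the proximal-contamination phenomenon the
package exists to study, and it is why the Full and Factored-out strategies
lose power inside inversions while LOCO does not.

### Summaries, exceedance and enrichment

`summarize_bins()` partitions scored variants by (arm, region) — region
being inside an inversion or outside, with breakpoint-buffer variants
counted as outside, since the binning is binary — and reports the hit
proportion (p below a threshold, default 1e−5) and the genomic inflation
factor: the median per-variant χ² divided by the χ²₁ median ≈ 0.4549. The χ²
values are recovered from p-values through the χ²₁ quantile function, so the
summary works on any p-value source; for score tests the transform is the
identity.

Every permutation comparison in the package uses the same rule: the observed
statistic *exceeds* when it is strictly greater than the 95th order
statistic of the permutation sample (for 100 permutations, the 95th
smallest). With 100 permutations this fires on exchangeable data with
probability 5/101 ≈ 4.95%; the acceptance suite confirms the empirical rate
is compatible with 5% for hit proportions, GIFs and enrichment odds ratios.
One practical note: the hit proportion is a count statistic, and at desk
scale (hundreds of variants) a 1e−5 threshold makes it almost always zero,
so the calibration check runs at a 0.05 hit threshold where the statistic is
quasi-continuous. Binomial confidence intervals on exceedance proportions
use the Wilson method.

Method and region contrasts (`compare_exceedance_fet()`,
`enrichment_fet()`) are two-sided Fisher's exact tests on 2×2 tables, with
the sample odds ratio reported and a Haldane correction (0.5 per cell) when
a cell is zero. Candidate-outlier sets (population-differentiation XtX* or
environmental-association Bayes factors) are consumed as an input contract —
a table of per-variant values and empirical p-values, outliers being those
below 0.05 — and the synthetic module fabricates such sets with controlled
regional enrichment; the upstream population-genomic scans themselves are
out of scope.

### Colocalization

`coloc_abf()` implements the standard five-hypothesis approximate-Bayes-
factor enumeration (no association; trait 1 only; trait 2 only; two distinct
causal variants; one shared causal variant) from per-SNP Wakefield log ABFs,

> log ABF = ½·log(1−r) + ½·r·z²,  r = W/(V+W),

with per-SNP priors p1 = p2 = 1e−4, p12 = 1e−5. Everything is computed in
log space; the distinct-causal-pair term is a direct pairwise log-sum-exp
rather than the algebraic identity S1+S2−S12, because the identity cancels
catastrophically when one SNP dominates both traits. The implementation
matches an exhaustive linear-space enumeration over causal configurations to
1e−8 in log posterior, which the suite asserts on random 2–6 SNP windows.

`sliding_coloc()` tiles each arm with half-open 10 kb windows advancing by
5 kb, starting at the arm's first scored position rounded down to a step
multiple; windows with fewer than 5 SNPs scored in both runs are flagged and
skipped. The effect-size prior sd defaults to 0.15 × sd(trait), the
quantitative-trait convention, with the trait sd recorded on each GWA run.

### Trait-space PCA

Missing trait means are imputed by regularized iterative PCA
(`impute_regularized_pca()`): fill with column means; iterate center/scale,
rank-ncp SVD with singular values shrunk by λ ← (λ² − σ̂²)/λ, rebuild,
restore scale, overwrite only the originally missing cells. The noise
estimate σ̂² is the energy of the discarded singular values divided by the
residual degrees of freedom (n−1)p − (n−1)·ncp − p·ncp + ncp². The exact
regularization variant used by reference implementations is not pinned down
publicly, so this estimator is validated by its recovery properties instead
of cell-for-cell agreement with any one tool: noiseless rank-1 matrices are
completed to 1e−6, and on rank-3-plus-noise matrices the masked-cell RMSE
beats column-mean imputation in the large majority of replicates.

`pca_traits()` is correlation-based (unit-variance scaling), because the
trait compendium mixes units as different as bristle counts and lifespans;
this is the single biggest fidelity assumption of the trait-space analysis
and is deliberately symmetric with the scaling used inside the imputation.
`ncp` defaults to 2 since only the top two components are analyzed
downstream. Karyotype contrasts on the projections use Welch's
unequal-variance t-test (the reference analyses report fractional degrees of
freedom, which identifies the Welch form). Trait sets for this module are
selected by the conjunction of the matched-null flag and a floor of 5%
INV-homozygous lines.

Both PCAs fix component signs so the largest-magnitude loading is positive,
making permutation comparisons and plots reproducible; genotype PCA
standardizes columns as (g − 2p)/√(2p(1−p)) and zeroes missing entries after
centering (mean imputation).

## The synthetic panel generator

`simulate_panel()` emulates the features of an inbred reference panel that
the analyses above rely on — and nothing more:

* ~200 fully inbred lines; dosages are 0/2 except that karyotypic
  heterozygotes (off by default) may carry dosage 1 inside the inversion;
* one or more inversions at intermediate frequency whose karyotype is in
  strong, distance-decaying LD with variants inside and near the inverted
  region. The tagging model is deliberately phenomenological: a variant at
  distance d from the nearest breakpoint mismatches its karyotype-tagged
  haplotype allele with probability leak(d) = min(leak₀ + d/ℓ, 0.5). With
  the defaults (leak₀ = 0.02, ℓ = 4 Mb) tagging decays to background about
  1.9 Mb past the breakpoints, inside the 2 Mb exclusion zone used by the
  matched null;
* a Beta(0.8, 3) allele-frequency spectrum for background variants (rare
  alleles common, as in sequence data), 3% missing genotypes completely at
  random, a binary *Wolbachia* covariate at 50%, and an optional
  two-source admixture proportion per line.

`simulate_traits()` builds y = Σβⱼgⱼ + β_w·wolbachia + β_inv·I(INV) + ε and
solves the *total* inversion coefficient against the variance of the
inversion-orthogonalized background, so the realized share of trait variance
attributable to the inversion equals the target `r2_inv`. The
orthogonalization matters: polygenic loci are drawn genome-wide and some are
inversion-tagged, so the naive solution overshoots the target. The default
target is 0.10 — the order of magnitude at which cosmopolitan inversions act
on line-mean traits in this system — and the acceptance suite verifies mean
realized R² ≈ 0.10 across hundreds of replicate traits.

What the generator does **not** emulate: recombination-map realism,
coalescent LD between background variants (they are exchangeable given their
frequencies), selection, demographic history, or genotyping error that is
correlated with karyotype. Consequently, passing tests demonstrate the
statistical machinery behaves as specified under the assumed structure; they
do not certify performance on real panels where background LD and population
substructure are richer.

### Seeds

One master seed governs a run. Every stochastic component derives a child
seed by a 31-bit polynomial hash of the master seed and a component label
(`child_seed()`), feeding R's Mersenne–Twister, which is platform-
independent. Adding traits therefore never perturbs genotype draws, and
fixed seeds reproduce panels, permutation matrices and whole scenario
directories bit for bit — all asserted in the suite.

## Numerical and design decisions

* **Coordinates** are 1-based inclusive for variants and breakpoints (VCF
  convention); colocalization windows are half-open.
* **Degenerate inputs**: constant variants are skipped with a reason;
  monomorphic variants after arm subsetting are dropped with a message;
  traits with fewer than two observed values, singular fixed-effect
  designs, and karyotype classes with fewer than two homozygotes raise
  errors.
* **Missing data**: karyotype calls are never imputed — missing calls simply
  exclude a line from inversion-conditioned analyses. Missing dosages are
  mean-imputed in the GRM/PCA/score stages (per-variant exclusion is the
  GCTA pairwise path); missing trait means are imputed only in the
  trait-PCA module, by the regularized algorithm above.
* **Factored-out inversion list** is configurable and defaults to every
  inversion in the karyotype table; reference pipelines differ on which
  five or six inversions enter this regression.
* **Matched-variant homozygosity**: lines with dosage 1 at a matched
  variant are excluded from that draw, mirroring the homozygote-only rule
  of the inversion models; each null fit uses the matched variant's own
  homozygote subset.
* **Percentiles** are order statistics of the permutation sample, and
  "exceeds" is always strict.

## Problem sizes

The packaged tests and the acceptance script run on deliberately compact
instances chosen to keep the whole suite interactive while leaving every
statistical check well-powered: panels of 100–200 lines with 120–150
variants per arm for the GWA-level checks (2 arms), 500 variants per arm for
spectrum checks, a dense miniature genome (0.6 Mb arms, 600 variants) for
the 10 kb colocalization windows, 50–100 permutations per exceedance call,
and 30–500 replicates per Monte-Carlo recovery estimate. The end-to-end
demo scenario (`run_scenario()`) uses 80 lines, 100 variants per arm and 25
permutations.

## Known limitations

* The mixed model is Gaussian-only — appropriate for line means, not for
  binary or count phenotypes.
* Only one random effect (a single GRM) is supported; no multi-component
  partitioning.
* The LD pruner is the deterministic greedy scan described above; reference
  implementations may retain slightly different (equally valid) sets.
* Inversion × inversion interactions and heterozygote effect models are out
  of scope, as is estimation of the candidate-outlier statistics themselves.
* X-chromosome dosage compensation needs no special handling in an inbred
  panel and receives none.
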