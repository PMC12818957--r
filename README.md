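# invgwas

Inversion-aware association mapping for inbred line panels.

## What problem this solves

Large chromosomal inversions (In(2L)t, In(3R)Mo, …) segregate at
intermediate frequency in *Drosophila melanogaster* and suppress
recombination in heterozygotes, so a whole arm's worth of variants travels
in linkage with the karyotype. In an inbred mapping panel such as the DGRP
this cuts both ways:

* the inversion acts like a single common variant of large effect on many
  line-mean traits, and
* the linked block dominates genome-wide relatedness estimates, so
  mixed-model GWAS that corrects for relatedness with a full-genome GRM
  absorbs — and thereby hides — association signal inside and near the
  inversion (*proximal contamination*).

`invgwas` is a toolkit for quantifying the first effect and working around
the second. It is aimed at quantitative geneticists analyzing homozygous
line panels with segregating inversions.

## What it computes

* **Inversion–trait models.** OLS of line means on an INV/STD indicator
  among homozygous lines, F-tested against the null, with a
  *matched-frequency polymorphism null*: the same model refit on variants
  matched to the inversion's allele frequency (±1%), on the same arm, > 2 Mb
  from the breakpoints. A trait is flagged inversion-associated when
  p < 0.05 **and** its R² strictly exceeds the 95th order statistic of the
  matched-variant R² values. Ancestry-vs-inversion model comparisons are
  included.
* **Relatedness.** VanRaden full-genome GRM; GCTA GRM on an LD-pruned set
  (r² < 0.2 within 5 kb, greedy deterministic scan); leave-one-chromosome-out
  (LOCO) sub-GRMs.
* **Mixed-model GWAS.** Exact single-random-effect REML
  (y = Xβ + b + ε, b ~ N(0, τ_g K)) via one eigendecomposition and 1-D
  profile optimization, then the variant-wise score test
  T = (g′Py)²/(g′Pg) ~ χ²₁, under four strategies: Full, LD, LOCO and
  Factored-out (trait residualized on inversion karyotypes). Per-trait
  permutations shuffle the trait and refit everything.
* **Summaries.** Per (arm, inside/outside-inversion) bins: hit proportion
  (p < 1e−5) and genomic inflation factor (median χ² / 0.4549), permutation
  exceedance at the strict 95th order statistic, Fisher's exact contrasts
  between methods and regions, and top-hit enrichment against candidate
  outlier sets (XtX*/BF-style tables are consumed, not computed).
* **Colocalization.** Wakefield-ABF five-hypothesis enumeration
  (PP0–PP4) over sliding 10 kb / 5 kb windows of two GWA runs (e.g. trait
  PC1 vs PC2).
* **Trait PCA.** Regularized iterative PCA imputation of missing line
  means, correlation-based PCA, Welch t-tests of karyotype on projections.
* **Synthetic panels.** A generator for inbred genotype panels with
  inversion-tagged haplotype structure (leak(d) = min(leak₀ + d/ℓ, 0.5)),
  karyotypes, covariates, and traits with a controlled inversion-
  attributable variance share — every stage of the pipeline is testable
  without downloads.

## Worked example

Simulate a 200-line panel with an In(2L)t-like inversion at frequency 0.25,
give one trait a 10% inversion-attributable variance share, and compare the
LOCO and Factored-out strategies:

```r
library(invgwas)

cfg <- sim_config(n_lines = 200, genome = c("2L" = 23e6, "2R" = 21e6),
                  inversions = inversion_def("In(2L)t", "2L", 2225744, 13154180),
                  n_variants = 300, seed = 20)
sim    <- simulate_panel(cfg)
traits <- simulate_traits(sim$panel, sim$karyotypes, sim$covariates,
                          trait_sim_config(n_traits = 1, r2_inv = 0.10, seed = 20))
y <- traits$values[, 1]; names(y) <- traits$line_ids

inversion_trait_lm(y, sim$karyotypes, "In(2L)t")
#> R2 = 0.093, F(1,187) = 19.1, p = 2.01e-05
matched_null(y, sim$karyotypes, "In(2L)t", sim$panel, sim$inversions,
             n_draws = 100, freq_tol = 0.05, seed = 20)
#> null R2 95th pct = 0.059; flagged = TRUE
#> (warns that the matched pool holds 17 variants at this density and
#>  falls back to sampling with replacement)
```

The trait recovers its generative R² (~0.10), and it is flagged: the
inversion explains more variance than frequency-matched single variants.
Now the strategy contrast:

```r
grms <- build_grms(sim$panel)
loco <- run_gwa(traits, sim$panel, sim$karyotypes, sim$covariates,
                method = "loco", grms = grms, n_perm = 0, seed = 20)[[1]]
fo   <- run_gwa(traits, sim$panel, sim$karyotypes, sim$covariates,
                method = "factored_out", grms = grms, n_perm = 0, seed = 20)[[1]]
summarize_bins(loco, sim$inversions)
#>   arm  region   n hit_proportion   gif
#> 1  2L  inside 165         0.0303 31.27
#> 2  2L outside 110         0.0000  1.81
#> 3  2R outside 234         0.0000  1.37
summarize_bins(fo, sim$inversions)
#>   arm  region   n hit_proportion   gif
#> 1  2L  inside 165              0 0.131
#> 2  2L outside 110              0 0.756
#> 3  2R outside 234              0 1.358
```

Inside the inversion, LOCO shows a strongly inflated signal bin (GIF 31,
3% of variants past 1e−5) while the Factored-out run is *deflated*
(GIF 0.13) — it has regressed the inversion out of the trait and the linked
variants can no longer associate. That asymmetry is the package's central
phenomenon.

An end-to-end scenario (simulate → GRMs → PCAs → inversion association →
GWA × methods → summaries → enrichment → colocalization, with TSV artifacts
and a provenance manifest) is one call:

```r
res <- run_scenario(run_config(seed = 1, out_dir = "invgwas_demo"))
```

or from a shell: `Rscript scripts/invgwas.R run --out invgwas_demo`.

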