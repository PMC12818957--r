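Package: invgwas
Title: Inversion-Aware Genome-Wide Association for Inbred Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the phenotypic impact of chromosomal
    inversions in inbred line panels and for comparing genome-wide
    association strategies that handle inversion-driven relatedness in
    different ways. Implements VanRaden and GCTA genomic relatedness
    matrices, leave-one-chromosome-out (LOCO) sub-matrices, LD pruning,
    genotype and trait principal component analysis with regularized
    iterative PCA imputation, per-trait inversion linear models with
    matched-frequency polymorphism nulls, a mixed-model score test with
    per-trait permutations, bin-level GWA summaries (hit proportions and
    genomic inflation factors) with permutation exceedance, Fisher's exact
    enrichment against candidate-outlier sets, and approximate-Bayes-factor
    colocalization over sliding windows. A synthetic inbred-panel generator
    with inversion-induced linkage disequilibrium makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
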