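## Synthetic inbred-line panel generator: karyotypes, genotypes with
## inversion-induced, distance-decaying LD, covariates, traits with a
## controlled inversion-attributable variance fraction, and stand-in
## candidate-outlier sets.

#' Simulation configuration for an inbred panel
#'
#' Defaults describe the study system the package targets: a DGRP-like panel
#' of ~200 fully inbred lines, five major chromosome arms, one cosmopolitan
#' inversion segregating at intermediate frequency, a rare-allele-skewed MAF
#' spectrum, and a few percent missing genotypes.
#'
#' The inversion's footprint on genotypes is a haplotype-tagging model: each
#' variant at distance `d` from the nearest breakpoint (`d = 0` inside the
#' inversion) mismatches its karyotype-tagged haplotype allele with
#' probability `leak(d) = min(leak0 + d / leak_length, 0.5)`; at
#' `leak(d) = 0.5` the variant is untagged and draws an allele frequency from
#' `Beta(maf_beta[1], maf_beta[2])`.  With the defaults, tagging decays to
#' background ~1.9 Mb beyond the breakpoints.
#'
#' @param n_lines number of inbred lines (default 200).
#' @param genome named vector of arm lengths in bp.
#' @param inversions an [inversion_def()]; default one In(2L)t-like inversion.
#' @param inv_freq inverted-allele frequency per inversion (default 0.25).
#' @param het_fraction probability a line is karyotypically heterozygous
#'   (default 0: the panel is inbred; nonzero only to exercise exclusions).
#' @param n_variants variants per arm (default 400).
#' @param maf_beta shape parameters of the Beta allele-frequency spectrum.
#' @param missing_rate MCAR genotype missingness (default 0.03).
#' @param leak0,leak_length intercept and decay length (bp) of the tagging
#'   leak function.
#' @param wolbachia_freq infection probability (default 0.5).
#' @param ancestry_beta Beta parameters of the admixture-proportion draw
#'   (default mean 0.2); `ancestry_shift` is added for INV-karyotype lines
#'   (first inversion) to mimic ancestry-inversion correlation (default 0).
#' @param ancestry_shift see `ancestry_beta`.
#' @param seed master seed; all draws derive child streams from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_lines = 200L,
                       genome = c("2L" = 23e6, "2R" = 21e6, "3L" = 24e6,
                                  "3R" = 28e6, "X" = 22e6),
                       inversions = inversion_def("In(2L)t", "2L",
                                                  2225744L, 13154180L),
                       inv_freq = 0.25,
                       het_fraction = 0,
                       n_variants = 400L,
                       maf_beta = c(0.8, 3),
                       missing_rate = 0.03,
                       leak0 = 0.02,
                       leak_length = 4e6,
                       wolbachia_freq = 0.5,
                       ancestry_beta = c(2, 8),
                       ancestry_shift = 0,
                       seed = 1L) {
  stopifnot(n_lines >= 2, all(genome > 0), inherits(inversions, "inversion_def"),
            all(inv_freq >= 0 & inv_freq < 1) || nrow(inversions) == 0,
            het_fraction >= 0, het_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1,
            leak0 >= 0, leak0 <= 0.5, leak_length > 0)
  if (!all(inversions$arm %in% names(genome)))
    stop("inversion arm(s) absent from genome map")
  if (any(inversions$end > genome[inversions$arm]))
    stop("inversion extends beyond its arm")
  structure(list(n_lines = as.integer(n_lines), genome = genome,
                 inversions = inversions,
                 inv_freq = rep_len(inv_freq, nrow(inversions)),
                 het_fraction = het_fraction,
                 n_variants = rep_len(as.integer(n_variants), length(genome)),
                 maf_beta = maf_beta, missing_rate = missing_rate,
                 leak0 = leak0, leak_length = leak_length,
                 wolbachia_freq = wolbachia_freq,
                 ancestry_beta = ancestry_beta,
                 ancestry_shift = ancestry_shift,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an inbred panel with inversion-induced LD
#'
#' Each line draws, per inversion, karyotype HET with probability
#' `het_fraction` and otherwise INV with probability `inv_freq` (else STD).
#' Variants inside an inversion or within its tagging zone carry a
#' karyotype-tagged haplotype allele (mismatching with probability
#' `leak(d)`); which haplotype carries the alternate allele is randomized per
#' variant, so tagged variants have folded MAF near `min(q, 1-q)`.  All
#' dosages are homozygous (0/2) except that HET lines may carry dosage 1 at
#' variants inside the inversion body.  Missingness is MCAR.  Output is
#' bit-identical for a fixed `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `panel` ([genotype_panel()]), `karyotypes`
#'   ([karyotype_table()]), `inversions` ([inversion_def()]) and `covariates`
#'   ([line_covariates()]).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_lines
  line_ids <- sprintf("line_%03d", seq_len(n))
  inv <- cfg$inversions

  # karyotypes, one independent stream per inversion
  call <- matrix(NA_character_, n, nrow(inv),
                 dimnames = list(line_ids, inv$name))
  for (k in seq_len(nrow(inv))) {
    q <- cfg$inv_freq[k]
    if (q * n < 2)
      warning("expected INV count below 2 for ", inv$name[k],
              "; inversion-conditioned analyses will be degenerate")
    call[, k] <- with_seed(child_seed(cfg$seed, "karyotype", inv$name[k]), {
      het <- stats::runif(n) < cfg$het_fraction
      homo <- ifelse(stats::runif(n) < q, "INV", "STD")
      ifelse(het, "HET", homo)
    })
  }

  # genotypes, one stream per arm
  dosage_blocks <- list()
  variant_blocks <- list()
  for (arm in names(cfg$genome)) {
    nv <- cfg$n_variants[match(arm, names(cfg$genome))]
    if (nv == 0) next
    blk <- with_seed(child_seed(cfg$seed, "genotypes", arm), {
      pos <- sort(sample.int(cfg$genome[[arm]], nv))
      arm_inv <- which(inv$arm == arm)
      dos <- matrix(0, n, nv)
      for (j in seq_len(nv)) {
        d <- Inf; k_near <- NA_integer_
        for (k in arm_inv) {
          dk <- if (pos[j] >= inv$start[k] && pos[j] <= inv$end[k]) 0 else
            min(abs(pos[j] - inv$start[k]), abs(pos[j] - inv$end[k]))
          if (dk < d) { d <- dk; k_near <- k }
        }
        leak <- if (is.na(k_near)) 0.5 else
          min(cfg$leak0 + d / cfg$leak_length, 0.5)
        if (leak < 0.5) {
          # tagged: alleles follow the karyotype haplotypes
          kary <- call[, k_near]
          alt_on_inv <- stats::runif(1) < 0.5
          hap_allele <- function(is_inv_hap) {
            base <- as.numeric(is_inv_hap == alt_on_inv)
            flip <- stats::runif(n) < leak
            ifelse(flip, 1 - base, base)
          }
          a1 <- hap_allele(kary == "INV")
          inside <- d == 0
          if (inside) {
            # HET lines carry one haplotype of each orientation
            a1 <- ifelse(kary == "HET", hap_allele(TRUE), a1)
            a2 <- ifelse(kary == "HET", hap_allele(FALSE), a1)
          } else a2 <- a1
          dos[, j] <- a1 + a2
        } else {
          p <- stats::rbeta(1, cfg$maf_beta[1], cfg$maf_beta[2])
          dos[, j] <- 2 * (stats::runif(n) < p)
        }
      }
      if (cfg$missing_rate > 0)
        dos[stats::runif(length(dos)) < cfg$missing_rate] <- NA
      list(pos = pos, dos = dos)
    })
    ids <- paste(arm, blk$pos, "A", "T", sep = "_")
    dimnames(blk$dos) <- list(line_ids, ids)
    dosage_blocks[[arm]] <- blk$dos
    variant_blocks[[arm]] <- data.frame(id = ids, arm = arm, pos = blk$pos,
                                        ref = "A", alt = "T",
                                        stringsAsFactors = FALSE)
  }
  dosage <- do.call(cbind, dosage_blocks)
  variants <- do.call(rbind, variant_blocks)
  rownames(variants) <- NULL

  covariates <- with_seed(child_seed(cfg$seed, "covariates"), {
    wol <- ifelse(stats::runif(n) < cfg$wolbachia_freq, "present", "absent")
    anc <- stats::rbeta(n, cfg$ancestry_beta[1], cfg$ancestry_beta[2])
    if (nrow(inv) > 0 && cfg$ancestry_shift != 0)
      anc <- pmin(1, pmax(0, anc + cfg$ancestry_shift * (call[, 1] == "INV")))
    line_covariates(line_ids, wol, anc)
  })

  list(panel = genotype_panel(dosage, variants),
       karyotypes = karyotype_table(call),
       inversions = inv,
       covariates = covariates)
}

#' Trait-simulation configuration
#'
#' @param n_traits number of traits (default 20).
#' @param r2_inv target inversion-attributable variance fraction in `[0, 1)`,
#'   recycled per trait.  Default 0.10, the magnitude at which cosmopolitan
#'   inversions typically act on line-mean traits in this system.
#' @param inversion name of the inversion each trait loads on (recycled);
#'   default the first inversion.
#' @param share_sign sign (+1/-1) of each trait's inversion loading,
#'   recycled; default alternating, so the shared axis has mixed loadings.
#' @param n_poly number of polygenic loci per trait (default 50).
#' @param poly_scale sd of per-locus polygenic effects (default 0.08).
#' @param wolbachia_effect additive shift for infected lines (default 0.25).
#' @param resid_sd residual (environmental + measurement) sd (default 1).
#' @param trait_missing MCAR missingness of trait means (default 0.05).
#' @param seed master seed for the trait streams.
#' @return a `trait_sim_config` list.
#' @export
trait_sim_config <- function(n_traits = 20L, r2_inv = 0.10, inversion = NULL,
                             share_sign = NULL, n_poly = 50L,
                             poly_scale = 0.08, wolbachia_effect = 0.25,
                             resid_sd = 1, trait_missing = 0.05, seed = 1L) {
  stopifnot(n_traits >= 1, all(r2_inv >= 0 & r2_inv < 1),
            trait_missing >= 0, trait_missing < 1, resid_sd >= 0)
  if (is.null(share_sign)) share_sign <- rep_len(c(1, -1), n_traits)
  structure(list(n_traits = as.integer(n_traits),
                 r2_inv = rep_len(r2_inv, n_traits),
                 inversion = inversion,
                 share_sign = rep_len(share_sign, n_traits),
                 n_poly = as.integer(n_poly), poly_scale = poly_scale,
                 wolbachia_effect = wolbachia_effect, resid_sd = resid_sd,
                 trait_missing = trait_missing, seed = as.integer(seed)),
            class = "trait_sim_config")
}

#' Simulate line-mean traits with an inversion-attributable variance share
#'
#' Each trait is `y = beta_inv * I(karyotype == INV) + Z beta_poly +
#' beta_w * wolbachia + eps`, with `beta_inv` solved against the realized
#' variances of the non-inversion components so that the expected share of
#' trait variance attributable to the inversion equals `r2_inv`.  Traits are
#' assigned the five standard category labels cyclically.
#'
#' @param panel,karyotypes,covariates outputs of [simulate_panel()].
#' @param cfg a [trait_sim_config()].
#' @return a [trait_matrix()].
#' @export
simulate_traits <- function(panel, karyotypes, covariates, cfg) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(karyotypes, "karyotype_table"),
            inherits(cfg, "trait_sim_config"))
  if (!identical(panel$line_ids, karyotypes$line_ids))
    stop("panel and karyotypes must share line_ids")
  n <- length(panel$line_ids)
  inv_name <- cfg$inversion %||% karyotypes$inversions[1]
  if (!inv_name %in% karyotypes$inversions)
    stop("unknown inversion: ", inv_name)
  kary <- karyotypes$call[, inv_name]
  i_inv <- as.numeric(!is.na(kary) & kary == "INV")
  wolb <- as.numeric(covariates$wolbachia == "present")
  wolb[is.na(wolb)] <- 0

  # mean-imputed dosages for the polygenic background
  dos <- panel$dosage
  mu <- colMeans(dos, na.rm = TRUE)
  for (j in seq_len(ncol(dos))) dos[is.na(dos[, j]), j] <- mu[j]

  values <- matrix(NA_real_, n, cfg$n_traits,
                   dimnames = list(panel$line_ids,
                                   sprintf("trait_%02d", seq_len(cfg$n_traits))))
  for (t in seq_len(cfg$n_traits)) {
    values[, t] <- with_seed(child_seed(cfg$seed, "trait", t), {
      loci <- sample.int(ncol(dos), min(cfg$n_poly, ncol(dos)))
      beta <- stats::rnorm(length(loci), 0, cfg$poly_scale)
      base <- drop(dos[, loci, drop = FALSE] %*% beta) +
        cfg$wolbachia_effect * wolb +
        stats::rnorm(n, 0, cfg$resid_sd)
      r2 <- cfg$r2_inv[t]
      if (r2 > 0) {
        v_inv <- stats::var(i_inv)
        if (!is.finite(v_inv) || v_inv == 0)
          stop("target r2_inv > 0 but inversion indicator has no variance ",
               "(is its frequency 0 or 1?)")
        # the polygenic background includes inversion-tagged loci, so it is
        # itself correlated with the karyotype; solve for the *total*
        # inversion coefficient against the orthogonal residual variance so
        # the realized variance share equals the target
        gamma <- stats::cov(base, i_inv) / v_inv
        v_e <- stats::var(base - gamma * i_inv)
        b_tot <- cfg$share_sign[t] * sqrt(r2 / (1 - r2) * v_e / v_inv)
        base <- base + (b_tot - gamma) * i_inv
      }
      if (cfg$trait_missing > 0)
        base[stats::runif(n) < cfg$trait_missing] <- NA
      base
    })
  }
  cats <- c("Behavior", "Life-History", "Morphology", "Physiology",
            "Stress-resistance")
  trait_matrix(values, rep_len(cats, cfg$n_traits))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a candidate-outlier set with controlled regional enrichment
#'
#' Stand-in for externally computed population-differentiation (XtX*) or
#' environmental-association Bayes-factor outlier tables: variants are
#' flagged as outliers at base rate `frac_outliers`, multiplied by
#' `enrichment_factor` inside `enriched_region`, and each variant receives an
#' empirical p-value consistent with its flag (outliers below 0.05).
#'
#' @param variants variant metadata data.frame with columns `id`, `arm`,
#'   `pos` (e.g. `panel$variants`).
#' @param enriched_region an [inversion_def()] row describing the enriched
#'   interval.
#' @param frac_outliers base outlier rate in `[0, 1)`.
#' @param enrichment_factor rate multiplier inside the region (default 1).
#' @param statistic label, `"XtX*"` or `"BF"`.
#' @param seed integer seed.
#' @return a `candidate_set` data.frame: `id`, `statistic`, `value`,
#'   `empirical_p`, `outlier`.
#' @export
simulate_candidate_sets <- function(variants, enriched_region,
                                    frac_outliers, enrichment_factor = 1,
                                    statistic = c("XtX*", "BF"), seed = 1L) {
  statistic <- match.arg(statistic)
  stopifnot(frac_outliers >= 0, frac_outliers < 1, enrichment_factor >= 0)
  region <- classify_region(variants$arm, variants$pos, enriched_region,
                            buffer_bp = 0)
  rate <- pmin(1, frac_outliers * ifelse(region == "inside",
                                         enrichment_factor, 1))
  with_seed(child_seed(seed, "candidates", statistic), {
    outlier <- stats::runif(nrow(variants)) < rate
    p <- ifelse(outlier, stats::runif(nrow(variants), 0, 0.05),
                stats::runif(nrow(variants), 0.05, 1))
    candidate_set(variants$id, statistic, -log10(p), p)
  })
}

#' Construct a candidate-outlier set
#'
#' @param id variant ids.
#' @param statistic statistic name (`"XtX*"` or `"BF"`).
#' @param value per-variant statistic values.
#' @param empirical_p per-variant empirical p-values; the outlier flag is
#'   `empirical_p < 0.05` (surpassing 95% of the null distribution).
#' @return data.frame of class `candidate_set`.
#' @export
candidate_set <- function(id, statistic, value, empirical_p) {
  stopifnot(all(empirical_p >= 0 & empirical_p <= 1))
  out <- data.frame(id = as.character(id),
                    statistic = rep_len(statistic, length(id)),
                    value = value, empirical_p = empirical_p,
                    outlier = empirical_p < 0.05,
                    stringsAsFactors = FALSE)
  class(out) <- c("candidate_set", "data.frame")
  out
}
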