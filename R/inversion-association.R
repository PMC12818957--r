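## Per-trait inversion linear models on homozygous lines, the
## matched-frequency polymorphism null, the inversion-associated-trait flag,
## and the ancestry / inversion model comparisons.

#' Linear model of a trait on inversion karyotype
#'
#' OLS of the trait line means on an INV indicator among homozygous lines
#' (HET and missing karyotypes excluded, as the inverted-allele content of a
#' heterozygous inbred line is unknowable), compared with the intercept-only
#' model by an F test with df (1, n-2).
#'
#' @param trait_values named numeric vector of line means (names = line ids).
#' @param karyotypes a [karyotype_table()].
#' @param inversion inversion name.
#' @param trait optional trait label recorded on the result.
#' @return object of class `inversion_fit`: `trait`, `inversion`, `n`,
#'   `n_inv`, `n_std`, `beta` (INV - STD mean difference), `r2`, `f`, `p`.
#' @export
inversion_trait_lm <- function(trait_values, karyotypes, inversion,
                               trait = NA_character_) {
  stopifnot(inherits(karyotypes, "karyotype_table"))
  kary <- karyotypes$call[match(names(trait_values), karyotypes$line_ids),
                          inversion]
  use <- !is.na(kary) & kary %in% c("INV", "STD") & !is.na(trait_values)
  y <- trait_values[use]
  g <- as.numeric(kary[use] == "INV")
  if (sum(g == 1) < 2 || sum(g == 0) < 2)
    stop("need >= 2 homozygous lines per karyotype class (got ",
         sum(g == 1), " INV, ", sum(g == 0), " STD)")
  n <- length(y)
  r2 <- two_group_r2(y, g)
  f <- (n - 2) * r2 / (1 - r2)
  structure(list(trait = trait, inversion = inversion, n = n,
                 n_inv = sum(g == 1), n_std = sum(g == 0),
                 beta = mean(y[g == 1]) - mean(y[g == 0]),
                 r2 = r2, f = f,
                 p = stats::pf(f, 1, n - 2, lower.tail = FALSE)),
            class = "inversion_fit")
}

#' Matched-frequency polymorphism null for an inversion-trait model
#'
#' Asks whether the inversion explains more trait variation than comparable
#' single variants: the inversion model is re-fit on variants drawn from the
#' same chromosome arm, matched to the inversion's allele frequency within
#' `freq_tol`, lying outside the inversion body and more than `min_dist_bp`
#' from both breakpoints (where linkage to the inversion has decayed).  For
#' each draw the trait is regressed on dosage among lines homozygous at that
#' variant (dosage 0 or 2).  A trait is flagged inversion-associated when the
#' observed model is significant (p < 0.05) *and* its R-squared strictly
#' exceeds the 95th order statistic of the null R-squared values.
#'
#' @param trait_values named numeric vector of line means.
#' @param karyotypes a [karyotype_table()].
#' @param inversion inversion name (must appear in `inversions`).
#' @param panel a [genotype_panel()] supplying the matched-variant pool.
#' @param inversions an [inversion_def()] table with the breakpoints.
#' @param n_draws matched variants to draw (default 100; sampling is without
#'   replacement, falling back to with-replacement with a warning when the
#'   pool is smaller).
#' @param freq_tol frequency-matching tolerance (default 0.01).
#' @param min_dist_bp minimum distance from either breakpoint (default 2 Mb).
#' @param freq_mode inversion "frequency" definition used for matching:
#'   `"allele"` counts heterozygous calls, `f = (2 nINV + nHET) / (2 n)`;
#'   `"homozygote"` uses the proportion of INV homozygotes among called
#'   lines.
#' @param seed integer seed for the draw stream.
#' @param trait optional trait label.
#' @return object of class `matched_null_result`: the observed
#'   `inversion_fit`, `null_r2` and `null_p` vectors, `r2_q95`,
#'   `significant`, `exceeds_null`, `flagged_associated`, and the sampled
#'   variant ids.
#' @export
matched_null <- function(trait_values, karyotypes, inversion, panel,
                         inversions, n_draws = 100L, freq_tol = 0.01,
                         min_dist_bp = 2000000L,
                         freq_mode = c("allele", "homozygote"),
                         seed = 1L, trait = NA_character_) {
  freq_mode <- match.arg(freq_mode)
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(inversions, "inversion_def"))
  obs <- inversion_trait_lm(trait_values, karyotypes, inversion, trait)
  inv <- inversions[inversions$name == inversion, ]
  if (nrow(inv) != 1) stop("inversion not found in inversion_def: ", inversion)

  kary <- karyotypes$call[, inversion]
  called <- !is.na(kary)
  f <- if (freq_mode == "allele")
    (2 * sum(kary[called] == "INV") + sum(kary[called] == "HET")) /
      (2 * sum(called))
  else mean(kary[called] == "INV")
  f_folded <- min(f, 1 - f)

  v <- panel$variants
  dist <- pmin(abs(v$pos - inv$start), abs(v$pos - inv$end))
  inside <- v$pos >= inv$start & v$pos <= inv$end
  pool <- which(v$arm == inv$arm & !inside & dist > min_dist_bp &
                  abs(v$maf - f_folded) <= freq_tol)
  if (length(pool) == 0)
    stop("empty matched-variant pool (arm ", inv$arm, ", |maf - ",
         round(f_folded, 3), "| <= ", freq_tol, ", > ", min_dist_bp,
         " bp from breakpoints)")
  replace <- length(pool) < n_draws
  if (replace)
    warning("matched pool (", length(pool), ") smaller than n_draws (",
            n_draws, "); sampling with replacement")
  drawn <- with_seed(child_seed(seed, "matched_null", inversion),
                     sample(pool, n_draws, replace = replace))

  null_r2 <- null_p <- rep(NA_real_, n_draws)
  y_all <- trait_values[match(panel$line_ids, names(trait_values))]
  for (i in seq_along(drawn)) {
    g <- panel$dosage[, drawn[i]]
    use <- !is.na(g) & g %in% c(0, 2) & !is.na(y_all)
    y <- y_all[use]; gi <- g[use] / 2
    if (sum(gi == 1) < 2 || sum(gi == 0) < 2) next  # documented shortfall
    n <- length(y)
    r2 <- two_group_r2(y, gi)
    null_r2[i] <- r2
    null_p[i] <- stats::pf((n - 2) * r2 / (1 - r2), 1, n - 2,
                           lower.tail = FALSE)
  }
  r2_q95 <- perm_quantile(null_r2)
  significant <- obs$p < 0.05
  exceeds <- is.finite(r2_q95) && obs$r2 > r2_q95
  structure(list(observed = obs, inv_freq = f, null_r2 = null_r2,
                 null_p = null_p, r2_q95 = r2_q95,
                 n_valid_draws = sum(is.finite(null_r2)),
                 variant_ids = v$id[drawn],
                 significant = significant, exceeds_null = exceeds,
                 flagged_associated = significant && exceeds),
            class = "matched_null_result")
}

#' Ancestry / inversion model comparison for one trait
#'
#' Fits, on homozygous lines with ancestry estimates, an Ancestry-only
#' model, an Inversion-only model, and a Full model (ancestry + inversion)
#' against the intercept-only null, plus the nested Full-vs-Ancestry and
#' Full-vs-Inversion F tests.  Permutations shuffle the trait values across
#' lines; a model's exceedance flag is true when its observed R-squared
#' (or nested-test F) strictly exceeds the 95th order statistic of the
#' permuted values.
#'
#' @param trait_values named numeric vector of line means.
#' @param karyotypes a [karyotype_table()].
#' @param covariates a [line_covariates()] with `ancestry_african`.
#' @param inversion inversion name.
#' @param n_perm number of trait permutations (default 100).
#' @param seed integer seed.
#' @return object of class `ancestry_model_table`: data.frame `models` with
#'   one row per comparison (`model`, `r2`, `f`, `df1`, `df2`, `p`,
#'   `perm_q95`, `exceeds_95`), plus `n` and `n_dropped`.
#' @export
ancestry_models <- function(trait_values, karyotypes, covariates, inversion,
                            n_perm = 100L, seed = 1L) {
  stopifnot(inherits(covariates, "line_covariates"))
  ids <- names(trait_values)
  kary <- karyotypes$call[match(ids, karyotypes$line_ids), inversion]
  anc <- covariates$ancestry_african[match(ids, covariates$line_id)]
  use <- !is.na(kary) & kary %in% c("INV", "STD") & !is.na(trait_values) &
    !is.na(anc)
  n_dropped <- sum(!is.na(kary) & kary %in% c("INV", "STD") &
                     !is.na(trait_values) & is.na(anc))
  if (n_dropped > 0)
    message(n_dropped, " line(s) dropped for missing ancestry")
  y <- trait_values[use]
  g <- as.numeric(kary[use] == "INV")
  a <- anc[use]
  if (sum(g == 1) < 2 || sum(g == 0) < 2)
    stop("need >= 2 homozygous lines per karyotype class")
  stats_for <- function(yy) ancestry_model_stats(yy, a, g)
  obs <- stats_for(y)
  perm <- matrix(NA_real_, n_perm, length(obs))
  if (n_perm > 0) {
    perm <- with_seed(child_seed(seed, "ancestry_models", inversion),
                      t(vapply(seq_len(n_perm),
                               function(i) stats_for(sample(y)),
                               numeric(length(obs)))))
    colnames(perm) <- names(obs)
  }
  stat_names <- c("ancestry_r2", "inversion_r2", "full_r2",
                  "full_vs_ancestry_f", "full_vs_inversion_f")
  q95 <- if (n_perm > 0) apply(perm[, stat_names, drop = FALSE], 2,
                               perm_quantile) else rep(NA_real_, 5)
  n <- length(y)
  models <- data.frame(
    model = c("ancestry_only", "inversion_only", "full",
              "full_vs_ancestry", "full_vs_inversion"),
    r2 = c(obs[["ancestry_r2"]], obs[["inversion_r2"]], obs[["full_r2"]],
           NA, NA),
    f = c(obs[["ancestry_f"]], obs[["inversion_f"]], obs[["full_f"]],
          obs[["full_vs_ancestry_f"]], obs[["full_vs_inversion_f"]]),
    df1 = c(1, 1, 2, 1, 1),
    df2 = c(n - 2, n - 2, n - 3, n - 3, n - 3),
    p = c(obs[["ancestry_p"]], obs[["inversion_p"]], obs[["full_p"]],
          obs[["full_vs_ancestry_p"]], obs[["full_vs_inversion_p"]]),
    perm_q95 = q95,
    stringsAsFactors = FALSE)
  models$exceeds_95 <- c(obs[stat_names] > q95)
  structure(list(models = models, inversion = inversion, n = n,
                 n_dropped = n_dropped, n_perm = n_perm),
            class = "ancestry_model_table")
}

# R2, F and p for the three models plus nested comparisons; returns a named
# numeric vector so permutation replicates can be stacked.
ancestry_model_stats <- function(y, a, g) {
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  rss <- function(X) {
    fit <- stats::lm.fit(cbind(1, X), y)
    sum(fit$residuals^2)
  }
  rss_a <- rss(a); rss_g <- rss(g); rss_f <- rss(cbind(a, g))
  r2_a <- 1 - rss_a / tss; r2_g <- 1 - rss_g / tss; r2_f <- 1 - rss_f / tss
  f_of <- function(rss0, rss1, df_extra, df_res) {
    pmax((rss0 - rss1) / df_extra / (rss1 / df_res), 0)
  }
  f_a <- f_of(tss, rss_a, 1, n - 2)
  f_g <- f_of(tss, rss_g, 1, n - 2)
  f_f <- f_of(tss, rss_f, 2, n - 3)
  f_fa <- f_of(rss_a, rss_f, 1, n - 3)
  f_fg <- f_of(rss_g, rss_f, 1, n - 3)
  c(ancestry_r2 = r2_a, ancestry_f = f_a,
    ancestry_p = stats::pf(f_a, 1, n - 2, lower.tail = FALSE),
    inversion_r2 = r2_g, inversion_f = f_g,
    inversion_p = stats::pf(f_g, 1, n - 2, lower.tail = FALSE),
    full_r2 = r2_f, full_f = f_f,
    full_p = stats::pf(f_f, 2, n - 3, lower.tail = FALSE),
    full_vs_ancestry_f = f_fa,
    full_vs_ancestry_p = stats::pf(f_fa, 1, n - 3, lower.tail = FALSE),
    full_vs_inversion_f = f_fg,
    full_vs_inversion_p = stats::pf(f_fg, 1, n - 3, lower.tail = FALSE))
}
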