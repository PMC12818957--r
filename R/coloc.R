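## Approximate-Bayes-factor colocalization of two traits over sliding
## genomic windows.

#' Wakefield approximate Bayes factor
#'
#' For a variant with effect estimate `beta`, standard error `se`
#' (`V = se^2`, `z = beta/se`) and effect-size prior sd `prior_sd`
#' (`W = prior_sd^2`), the log ABF against the null is
#' `0.5 * log(1 - r) + 0.5 * r * z^2` with `r = W / (V + W)`.
#'
#' @param beta,se effect estimates and standard errors (vectors; `se > 0`).
#' @param prior_sd prior standard deviation of the true effect
#'   (default 0.15, the quantitative-trait convention).
#' @return numeric vector of log approximate Bayes factors.
#' @export
abf_wakefield <- function(beta, se, prior_sd = 0.15) {
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se <= 0))
    stop("beta/se must be finite with se > 0")
  V <- se^2
  W <- prior_sd^2
  r <- W / (V + W)
  z <- beta / se
  0.5 * log(1 - r) + 0.5 * r * z^2
}

log_sum_exp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Colocalization posteriors from two sets of per-SNP summary statistics
#'
#' Enumerates the five hypotheses — H0 no association, H1 trait-1 only,
#' H2 trait-2 only, H3 two distinct causal variants, H4 one shared causal
#' variant — from per-SNP Wakefield log ABFs, weighting by the per-SNP
#' priors and normalizing in log space.
#'
#' @param stats1,stats2 data.frames over the same SNPs (matched by `id`)
#'   with columns `id`, `beta`, `se`; or columns `id`, `labf` with
#'   precomputed log ABFs.
#' @param p1,p2,p12 per-SNP prior probabilities of association with trait 1
#'   only, trait 2 only, and both (defaults 1e-4, 1e-4, 1e-5).
#' @param prior_sd1,prior_sd2 effect-size prior sds passed to
#'   [abf_wakefield()] when `labf` is not supplied.
#' @return named vector `PP0`..`PP4` (sums to 1) with attribute `n_snps`.
#' @export
coloc_abf <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd1 = 0.15, prior_sd2 = 0.15) {
  if (!setequal(stats1$id, stats2$id) ||
        length(stats1$id) != length(stats2$id))
    stop("snp universes disagree: ",
         paste(utils::head(c(setdiff(stats1$id, stats2$id),
                             setdiff(stats2$id, stats1$id)), 5),
               collapse = ", "))
  stats2 <- stats2[match(stats1$id, stats2$id), , drop = FALSE]
  get_labf <- function(s, w) {
    if (!is.null(s$labf)) s$labf else abf_wakefield(s$beta, s$se, w)
  }
  l1 <- get_labf(stats1, prior_sd1)
  l2 <- get_labf(stats2, prior_sd2)
  s1 <- log_sum_exp(l1)
  s2 <- log_sum_exp(l2)
  s12 <- log_sum_exp(l1 + l2)            # shared causal snp
  # distinct causal snps: direct pairwise log-sum-exp over i != j (the
  # subtraction identity S1 + S2 - S12 cancels catastrophically when one
  # snp dominates both traits)
  pairs <- outer(l1, l2, "+")
  diag(pairs) <- -Inf
  s3 <- log_sum_exp(pairs)
  lh <- c(PP0 = 0,
          PP1 = log(p1) + s1,
          PP2 = log(p2) + s2,
          PP3 = log(p1) + log(p2) + s3,
          PP4 = log(p12) + s12)
  pp <- exp(lh - log_sum_exp(lh))
  pp <- pp / sum(pp)
  attr(pp, "n_snps") <- length(l1)
  pp
}

#' Sliding-window colocalization of two GWA runs
#'
#' Windows of width `window` bp advance by `step` bp along each arm
#' (half-open intervals, starting at the arm's first scored position rounded
#' down to a step multiple); each window with at least `min_snps` SNPs
#' scored in both runs is assigned [coloc_abf()] posteriors and classified
#' by the maximum-posterior hypothesis.  Effect estimates and standard
#' errors come from the score test; the effect-size prior sd defaults to
#' `0.15 * sd(trait)` per run, the quantitative-trait convention.
#'
#' @param run1,run2 `gwa_run` objects over the same variant universe
#'   (e.g. PC1 and PC2 projections scored with one strategy).
#' @param window,step window width and step in bp (defaults 10000 and 5000).
#' @param p1,p2,p12 colocalization priors (see [coloc_abf()]).
#' @param min_snps minimum SNPs per window (default 5; smaller windows are
#'   reported with `skipped = TRUE` and NA posteriors).
#' @param prior_sd1,prior_sd2 effect-size prior sds; default
#'   `0.15 * trait_sd` recorded on each run.
#' @return data.frame: `arm`, `start`, `end`, `n_snps`, `PP0`..`PP4`,
#'   `top` (argmax hypothesis), `skipped`.
#' @export
sliding_coloc <- function(run1, run2, window = 10000L, step = 5000L,
                          p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, min_snps = 5L,
                          prior_sd1 = NULL, prior_sd2 = NULL) {
  r1 <- run1$results; r2 <- run2$results
  if (!identical(r1$id, r2$id))
    stop("runs must share a variant universe")
  prior_sd1 <- prior_sd1 %||% (0.15 * run1$trait_sd)
  prior_sd2 <- prior_sd2 %||% (0.15 * run2$trait_sd)
  ok <- !is.na(r1$beta) & !is.na(r2$beta) & r1$se > 0 & r2$se > 0
  out <- list()
  for (arm in unique(r1$arm)) {
    sel <- which(ok & r1$arm == arm)
    if (length(sel) == 0) next
    pos <- r1$pos[sel]
    first <- floor(min(pos) / step) * step
    starts <- seq(first, max(pos), by = step)
    for (s in starts) {
      in_win <- sel[pos >= s & pos < s + window]
      if (length(in_win) < min_snps) {
        out[[length(out) + 1]] <- data.frame(
          arm = arm, start = s, end = s + window,
          n_snps = length(in_win), PP0 = NA_real_, PP1 = NA_real_,
          PP2 = NA_real_, PP3 = NA_real_, PP4 = NA_real_,
          top = NA_character_, skipped = TRUE, stringsAsFactors = FALSE)
        next
      }
      pp <- coloc_abf(
        data.frame(id = r1$id[in_win], beta = r1$beta[in_win],
                   se = r1$se[in_win], stringsAsFactors = FALSE),
        data.frame(id = r2$id[in_win], beta = r2$beta[in_win],
                   se = r2$se[in_win], stringsAsFactors = FALSE),
        p1 = p1, p2 = p2, p12 = p12,
        prior_sd1 = prior_sd1, prior_sd2 = prior_sd2)
      out[[length(out) + 1]] <- data.frame(
        arm = arm, start = s, end = s + window, n_snps = length(in_win),
        PP0 = pp[["PP0"]], PP1 = pp[["PP1"]], PP2 = pp[["PP2"]],
        PP3 = pp[["PP3"]], PP4 = pp[["PP4"]],
        top = names(pp)[which.max(pp)], skipped = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
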