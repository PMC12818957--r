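## Bin-level GWA summary statistics (hit proportion, genomic inflation
## factor), permutation exceedance, and Fisher's-exact comparisons of
## exceedance rates between methods or regions.

# median of the chi-squared(1) distribution; the GIF denominator
CHISQ1_MEDIAN <- stats::qchisq(0.5, df = 1)

#' Bin-level summaries of a GWA run
#'
#' Partitions scored variants by (arm, region) — region being `inside` an
#' inversion or `outside` (breakpoint-buffer variants count as outside; the
#' binning is binary) — and reports per bin the proportion of "hits"
#' (p < `p_threshold`) and the genomic inflation factor: the median
#' per-variant chi-squared statistic (recovered from p via the chi-squared(1)
#' quantile function, so any p-value source works) divided by the
#' chi-squared(1) median, ~0.4549.
#'
#' @param run a `gwa_run` from [run_gwa()], or a data.frame with columns
#'   `arm`, `pos`, `p`.
#' @param inversions an [inversion_def()] table.
#' @param p_threshold hit threshold (default 1e-5).
#' @param p_override optional replacement p-value vector (used internally to
#'   summarize permutation replicates on the same variant universe).
#' @return data.frame: `trait`, `method`, `arm`, `region`, `n`,
#'   `hit_proportion`, `gif`, `empty` flag.
#' @export
summarize_bins <- function(run, inversions, p_threshold = 1e-5,
                           p_override = NULL) {
  if (inherits(run, "gwa_run")) {
    res <- run$results; trait <- run$trait; method <- run$method
  } else {
    res <- run; trait <- NA_character_; method <- NA_character_
  }
  p <- if (is.null(p_override)) res$p else p_override
  region <- classify_region(res$arm, res$pos, inversions)
  region <- ifelse(region == "inside", "inside", "outside")
  keep <- !is.na(p)
  bins <- unique(data.frame(arm = res$arm, region = region,
                            stringsAsFactors = FALSE))
  bins <- bins[order(bins$arm, bins$region), ]
  out <- lapply(seq_len(nrow(bins)), function(i) {
    sel <- keep & res$arm == bins$arm[i] & region == bins$region[i]
    n <- sum(sel)
    if (n == 0)
      return(data.frame(trait = trait, method = method, arm = bins$arm[i],
                        region = bins$region[i], n = 0L,
                        hit_proportion = NA_real_, gif = NA_real_,
                        empty = TRUE, stringsAsFactors = FALSE))
    chisq <- stats::qchisq(p[sel], df = 1, lower.tail = FALSE)
    data.frame(trait = trait, method = method, arm = bins$arm[i],
               region = bins$region[i], n = n,
               hit_proportion = mean(p[sel] < p_threshold),
               gif = stats::median(chisq) / CHISQ1_MEDIAN,
               empty = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bin summaries for every permutation replicate of a run
#'
#' @param run a `gwa_run` with a `perm_p` matrix.
#' @inheritParams summarize_bins
#' @return list of [summarize_bins()] data.frames, one per permutation.
#' @export
summarize_bins_perms <- function(run, inversions, p_threshold = 1e-5) {
  stopifnot(inherits(run, "gwa_run"), !is.null(run$perm_p))
  lapply(seq_len(ncol(run$perm_p)), function(r)
    summarize_bins(run, inversions, p_threshold,
                   p_override = run$perm_p[, r]))
}

#' Permutation exceedance of bin summaries
#'
#' For each bin and each statistic (`hits`, `gif`), the observed value
#' exceeds when it is strictly greater than the empirical `q`-th order
#' statistic of the permuted values (for 100 permutations and q = 0.95, the
#' 95th smallest).
#'
#' @param observed a [summarize_bins()] data.frame.
#' @param permuted a list of [summarize_bins()] data.frames over the same
#'   bins (fewer than 20 triggers a warning).
#' @param q order-statistic level (default 0.95).
#' @return data.frame: bin columns plus `statistic`, `observed`, `perm_q`,
#'   `exceeds`, `n_perm`.
#' @export
exceedance <- function(observed, permuted, q = 0.95) {
  if (length(permuted) < 20)
    warning("fewer than 20 permutations; exceedance calls will be coarse")
  key <- function(d) paste(d$arm, d$region)
  for (d in permuted)
    if (!identical(key(d), key(observed))) stop("mismatched bins")
  out <- lapply(c(hits = "hit_proportion", gif = "gif"), function(col) {
    perm_mat <- vapply(permuted, function(d) d[[col]],
                       numeric(nrow(observed)))
    perm_mat <- matrix(perm_mat, nrow = nrow(observed))
    qv <- apply(perm_mat, 1, perm_quantile, q = q)
    data.frame(trait = observed$trait, method = observed$method,
               arm = observed$arm, region = observed$region,
               observed = observed[[col]], perm_q = qv,
               exceeds = !is.na(observed[[col]]) & !is.na(qv) &
                 observed[[col]] > qv,
               n_perm = length(permuted), stringsAsFactors = FALSE)
  })
  out$hits$statistic <- "hits"
  out$gif$statistic <- "gif"
  rbind(out$hits, out$gif)
}

#' Fisher's exact comparison of exceedance rates
#'
#' Builds the 2x2 table of (exceeds / not) x (group A / group B) across
#' traits and returns the sample odds ratio with a two-sided exact p-value.
#' Zero-margin tables report the raw OR (possibly 0 or Inf) plus a
#' Haldane-corrected auxiliary value (0.5 added to each cell).
#'
#' @param exceeds_a,exceeds_b logical vectors of per-trait exceedance calls
#'   for the two groups (same trait set; e.g. two methods, or the same
#'   method in inside vs outside regions).
#' @return list: `table` (2x2), `odds_ratio` (sample ad/bc),
#'   `odds_ratio_haldane`, `p` (two-sided Fisher).
#' @export
compare_exceedance_fet <- function(exceeds_a, exceeds_b) {
  exceeds_a <- exceeds_a[!is.na(exceeds_a)]
  exceeds_b <- exceeds_b[!is.na(exceeds_b)]
  tab <- rbind(A = c(yes = sum(exceeds_a), no = sum(!exceeds_a)),
               B = c(yes = sum(exceeds_b), no = sum(!exceeds_b)))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  or_h <- ((tab[1, 1] + .5) * (tab[2, 2] + .5)) /
    ((tab[1, 2] + .5) * (tab[2, 1] + .5))
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, odds_ratio = or, odds_ratio_haldane = or_h, p = p)
}

#' Wilson score confidence interval for a proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return named vector: `estimate`, `lower`, `upper`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(estimate = NA_real_, lower = NA_real_,
                       upper = NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- x / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(estimate = phat, lower = max(0, center - half),
    upper = min(1, center + half))
}
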