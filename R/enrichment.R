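## Enrichment of top GWA hits in externally supplied (or simulated)
## candidate-outlier sets, with permutation-based exceedance.

#' Top GWA hits
#'
#' The `k` variants with the smallest p-values; ties at the boundary are
#' broken by (arm, pos) lexicographic order so the selection is
#' deterministic.
#'
#' @param run a `gwa_run` (or its `results` data.frame).
#' @param k number of hits (default 500); if fewer variants were scored,
#'   all are returned with a warning.
#' @param p_override optional replacement p-values (permutation replicates).
#' @return character vector of variant ids.
#' @export
top_hits <- function(run, k = 500L, p_override = NULL) {
  res <- if (inherits(run, "gwa_run")) run$results else run
  p <- if (is.null(p_override)) res$p else p_override
  ok <- which(!is.na(p))
  if (length(ok) == 0) stop("no scored variants")
  if (length(ok) < k) {
    warning("only ", length(ok), " scored variants; returning all")
    k <- length(ok)
  }
  ord <- ok[order(p[ok], res$arm[ok], res$pos[ok])]
  res$id[ord[seq_len(k)]]
}

#' Fisher's exact enrichment of top hits in a candidate-outlier set
#'
#' 2x2 table of (in top set / not) x (outlier / not) over the variant
#' universe; returns the sample odds ratio (Haldane-corrected when a cell is
#' zero) and the two-sided exact p.
#'
#' @param top character vector of top-hit variant ids (subset of universe).
#' @param candidates a [candidate_set()] whose flags cover the universe.
#' @param universe character vector of variant ids (typically the scored
#'   variants of the GWA run).
#' @return list: `table`, `odds_ratio`, `odds_ratio_haldane`, `p`.
#' @export
enrichment_fet <- function(top, candidates, universe) {
  stopifnot(inherits(candidates, "candidate_set"))
  if (length(universe) == 0) stop("empty universe")
  if (!all(top %in% universe)) stop("top hits must be a subset of universe")
  flag <- candidates$outlier[match(universe, candidates$id)]
  if (anyNA(flag))
    stop("candidate flags undefined for ", sum(is.na(flag)),
         " universe variant(s)")
  in_top <- universe %in% top
  tab <- rbind(top = c(outlier = sum(in_top & flag),
                       other = sum(in_top & !flag)),
               rest = c(outlier = sum(!in_top & flag),
                        other = sum(!in_top & !flag)))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  or_h <- ((tab[1, 1] + .5) * (tab[2, 2] + .5)) /
    ((tab[1, 2] + .5) * (tab[2, 1] + .5))
  list(table = tab,
       odds_ratio = if (any(tab == 0)) or_h else or,
       odds_ratio_raw = or, odds_ratio_haldane = or_h,
       p = stats::fisher.test(tab)$p.value)
}

#' Permutation exceedance of an enrichment odds ratio
#'
#' @param observed_or observed odds ratio.
#' @param permuted_ors odds ratios from permuted GWA runs (fewer than 20
#'   triggers a warning; non-finite values are excluded with a count).
#' @param q order-statistic level (default 0.95).
#' @return list: `exceeds` (strictly greater than the q-th order statistic),
#'   `perm_q`, `n_used`, `n_excluded`.
#' @export
enrichment_exceedance <- function(observed_or, permuted_ors, q = 0.95) {
  ok <- is.finite(permuted_ors)
  if (sum(ok) < 20)
    warning("fewer than 20 usable permuted odds ratios")
  qv <- perm_quantile(permuted_ors[ok], q)
  list(exceeds = is.finite(observed_or) && observed_or > qv,
       perm_q = qv, n_used = sum(ok), n_excluded = sum(!ok))
}

#' Proportion of traits with enrichment exceedance, with Wilson CI
#'
#' @param exceeds logical vector of per-trait exceedance calls.
#' @param conf confidence level.
#' @return named vector: `estimate`, `lower`, `upper`, `n`.
#' @export
exceedance_proportion <- function(exceeds, conf = 0.95) {
  exceeds <- exceeds[!is.na(exceeds)]
  c(wilson_ci(sum(exceeds), length(exceeds), conf), n = length(exceeds))
}

#' @rdname io_tsv
#' @param candidates a [candidate_set()].
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io_tsv
#' @export
read_candidates <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  candidate_set(tab$id, tab$statistic, tab$value, tab$empirical_p)
}
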