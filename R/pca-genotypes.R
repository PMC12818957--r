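## PCA of genotype panels under the Full / LD / LOCO variant-selection
## strategies, linear models of inversion karyotype on PC scores with
## label-shuffling permutations, and relatedness summaries by karyotype pair.

#' Principal component analysis of a genotype panel
#'
#' Columns are standardized as `(g - 2p) / sqrt(2 p (1 - p))` with missing
#' entries set to 0 after centering (mean imputation); scores are the leading
#' eigenvectors of the line x line covariance scaled by the square root of
#' their eigenvalues.  The sign of each component is fixed so that its
#' largest-magnitude entry is positive, making permutation comparisons and
#' plots reproducible.
#'
#' @param panel a [genotype_panel()], already filtered per the strategy's
#'   recipe (see [select_variants()]).
#' @param n_components number of components to return (default 10, truncated
#'   to the matrix rank with a warning).
#' @param strategy tag recorded on the result, e.g. `"Full"`, `"LD"`,
#'   `"LOCO(2L)"`.
#' @return object of class `pca_result`: `scores` (lines x components),
#'   `eigenvalues` (all, non-increasing), `varexp` (fractions of total
#'   variance), `line_ids`, `strategy`.
#' @export
pca_genotypes <- function(panel, n_components = 10L, strategy = "Full") {
  stopifnot(inherits(panel, "genotype_panel"), length(panel$line_ids) >= 2)
  dos <- panel$dosage
  p <- colSums(dos, na.rm = TRUE) / (2 * colSums(!is.na(dos)))
  keep <- is.finite(p) & p > 0 & p < 1
  if (!all(keep)) {
    message("dropping ", sum(!keep), " monomorphic variant(s) before PCA")
    dos <- dos[, keep, drop = FALSE]
    p <- p[keep]
  }
  if (ncol(dos) == 0) stop("no polymorphic variants")
  A <- sweep(sweep(dos, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  A[is.na(A)] <- 0
  C <- tcrossprod(A) / ncol(A)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  rank <- sum(ev > max(ev) * 1e-12)
  if (n_components > rank) {
    warning("n_components (", n_components, ") exceeds rank (", rank,
            "); truncating")
    n_components <- rank
  }
  V <- e$vectors[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  scores <- sweep(V, 2, sqrt(ev[seq_len(n_components)]), "*")
  dimnames(scores) <- list(panel$line_ids,
                           paste0("PC", seq_len(n_components)))
  structure(list(scores = scores, eigenvalues = ev,
                 varexp = ev / sum(ev), line_ids = panel$line_ids,
                 strategy = strategy),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result (", x$strategy, "): ", length(x$line_ids), " lines, ",
      ncol(x$scores), " components; PC1 explains ",
      round(100 * x$varexp[1], 1), "%\n", sep = "")
  invisible(x)
}

# q-th order-statistic "percentile": for 100 draws and q = 0.95 this is the
# 95th smallest value.  Used for every permutation comparison in the package.
perm_quantile <- function(x, q = 0.95) {
  x <- x[is.finite(x)]
  sort(x)[ceiling(q * length(x))]
}

#' Linear model of a PC score on inversion karyotype, with permutations
#'
#' Ordinary least squares of the component score on an INV indicator among
#' homozygous lines only (HET and missing calls excluded); permutations
#' shuffle the karyotype labels among the included homozygotes.  The model is
#' called significant when its R-squared strictly exceeds the 95th
#' order statistic of the permutation R-squared values.
#'
#' @param pca a `pca_result` (or `trait_pca_result`).
#' @param karyotypes a [karyotype_table()].
#' @param inversion inversion name.
#' @param component component index (default 1).
#' @param n_perm number of karyotype permutations (default 100).
#' @param seed integer seed for the permutation stream.
#' @return object of class `pc_inversion_model`: `component`, `inversion`,
#'   `n`, `n_inv`, `n_std`, `r2`, `f`, `df`, `p`, `perm_r2`, `exceeds_95`.
#' @export
pc_inversion_model <- function(pca, karyotypes, inversion, component = 1L,
                               n_perm = 100L, seed = 1L) {
  stopifnot(inherits(karyotypes, "karyotype_table"))
  if (!inversion %in% karyotypes$inversions)
    stop("unknown inversion: ", inversion)
  score <- pca$scores[, component]
  kary <- karyotypes$call[match(pca$line_ids, karyotypes$line_ids), inversion]
  use <- !is.na(kary) & kary %in% c("INV", "STD") & !is.na(score)
  y <- score[use]
  g <- as.numeric(kary[use] == "INV")
  if (sum(g == 1) < 2 || sum(g == 0) < 2)
    stop("need >= 2 homozygous lines per karyotype class (got ",
         sum(g == 1), " INV, ", sum(g == 0), " STD)")
  n <- length(y)
  r2 <- two_group_r2(y, g)
  f <- (n - 2) * r2 / (1 - r2)
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  perm_r2 <- rep(NA_real_, n_perm)
  if (n_perm > 0) {
    perm_r2 <- with_seed(child_seed(seed, "pc_inversion", inversion, component),
                         vapply(seq_len(n_perm), function(i)
                           two_group_r2(y, sample(g)), numeric(1)))
  }
  structure(list(component = component, inversion = inversion,
                 n = n, n_inv = sum(g == 1), n_std = sum(g == 0),
                 r2 = r2, f = f, df = c(1, n - 2), p = p,
                 perm_r2 = perm_r2,
                 exceeds_95 = if (n_perm > 0) r2 > perm_quantile(perm_r2)
                 else NA),
            class = "pc_inversion_model")
}

# R^2 of y ~ binary indicator g: squared point-biserial correlation.
# 0 when y or g is constant.
two_group_r2 <- function(y, g) {
  if (stats::var(y) == 0 || stats::var(g) == 0) return(0)
  stats::cor(y, g)^2
}

#' Pairwise relatedness summarized by karyotype pair class
#'
#' Off-diagonal entries of a relatedness matrix are partitioned into INV/INV,
#' STD/STD and INV/STD pairs of homozygous lines (heterozygous and missing
#' calls excluded) and summarized.
#'
#' @param grm a [relatedness_matrix()].
#' @param karyotypes a [karyotype_table()].
#' @param inversion inversion name.
#' @return data.frame with one row per pair class: `pair_class`, `n_pairs`,
#'   `mean`, and the 5/25/50/75/95 percent quantiles.
#' @export
relatedness_by_karyotype <- function(grm, karyotypes, inversion) {
  stopifnot(inherits(grm, "relatedness_matrix"),
            inherits(karyotypes, "karyotype_table"))
  kary <- karyotypes$call[match(grm$line_ids, karyotypes$line_ids), inversion]
  classes <- list("INV/INV" = c("INV", "INV"),
                  "STD/STD" = c("STD", "STD"),
                  "INV/STD" = c("INV", "STD"))
  out <- lapply(names(classes), function(cl) {
    a <- which(!is.na(kary) & kary == classes[[cl]][1])
    b <- which(!is.na(kary) & kary == classes[[cl]][2])
    if (classes[[cl]][1] == classes[[cl]][2]) {
      vals <- if (length(a) >= 2) {
        pr <- utils::combn(a, 2)
        grm$K[cbind(pr[1, ], pr[2, ])]
      } else numeric(0)
    } else {
      vals <- as.vector(grm$K[a, b, drop = FALSE])
    }
    qs <- if (length(vals)) stats::quantile(vals, c(.05, .25, .5, .75, .95))
    else rep(NA_real_, 5)
    data.frame(pair_class = cl, n_pairs = length(vals),
               mean = if (length(vals)) mean(vals) else NA_real_,
               q05 = qs[[1]], q25 = qs[[2]], q50 = qs[[3]],
               q75 = qs[[4]], q95 = qs[[5]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
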