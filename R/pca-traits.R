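## Trait-space PCA: regularized iterative PCA imputation of missing trait
## means, correlation-based PCA, and Welch t-tests of karyotype on the
## component projections.

#' Regularized iterative PCA imputation of a trait matrix
#'
#' Missing cells are first filled with column means; the algorithm then
#' iterates: center and scale columns, take the rank-`ncp` SVD with
#' regularized singular values `lambda_k <- (lambda_k^2 - sigma2) / lambda_k`
#' (where `sigma2` is the sum of the discarded squared singular values
#' divided by the residual degrees of freedom
#' `(n-1) p - (n-1) ncp - p ncp + ncp^2`), rebuild the matrix, restore scale
#' and center, and overwrite only the originally missing cells.  Iteration
#' stops when the largest absolute change in an imputed cell falls below
#' `tol`.  Observed cells are never modified.  The regularization shrinks the
#' reconstruction toward the column means in proportion to the estimated
#' noise level, which prevents the overfitting that plain iterative SVD
#' imputation exhibits on noisy data.
#'
#' @param traits a [trait_matrix()] (every trait needs >= 2 observed values).
#' @param ncp number of components for the reconstruction (default 2);
#'   must be below `min(dim)`.
#' @param tol convergence tolerance on imputed cells (default 1e-6).
#' @param max_iter iteration cap (default 1000); non-convergence returns the
#'   current state with a warning and `converged = FALSE` in the metadata.
#' @return the completed [trait_matrix()], with an `"imputation"` attribute
#'   (list: `ncp`, `iterations`, `converged`, `n_imputed`).
#' @export
impute_regularized_pca <- function(traits, ncp = 2L, tol = 1e-6,
                                   max_iter = 1000L) {
  stopifnot(inherits(traits, "trait_matrix"), ncp >= 1)
  X <- traits$values
  n <- nrow(X); p <- ncol(X)
  if (ncp >= min(n, p)) stop("ncp must be < min(dim)")
  if (any(colSums(!is.na(X)) < 2))
    stop("every trait needs >= 2 observed values")
  miss <- is.na(X)
  meta <- list(ncp = as.integer(ncp), iterations = 0L, converged = TRUE,
               n_imputed = sum(miss))
  if (!any(miss)) {
    attr(traits, "imputation") <- meta
    return(traits)
  }
  mu0 <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(p)) X[miss[, j], j] <- mu0[j]

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- colMeans(X)
    s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, s, "/")
    sv <- svd(Xs)
    q <- length(sv$d)
    df_res <- (n - 1) * p - (n - 1) * ncp - p * ncp + ncp^2
    sigma2 <- if (q > ncp && df_res > 0)
      sum(sv$d[(ncp + 1):q]^2) / df_res else 0
    lam <- pmax((sv$d[seq_len(ncp)]^2 - sigma2) / sv$d[seq_len(ncp)], 0)
    fit <- sv$u[, seq_len(ncp), drop = FALSE] %*%
      (lam * t(sv$v[, seq_len(ncp), drop = FALSE]))
    fit <- sweep(sweep(fit, 2, s, "*"), 2, mu, "+")
    delta <- max(abs(fit[miss] - X[miss]))
    X[miss] <- fit[miss]
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("imputation did not converge in ", max_iter, " iterations")
  meta$iterations <- iter
  meta$converged <- converged
  out <- trait_matrix(X, traits$category)
  attr(out, "imputation") <- meta
  out
}

#' Correlation-based PCA of a completed trait matrix
#'
#' Columns are centered and scaled to unit variance (the traits have
#' heterogeneous units), then decomposed by SVD.  Loadings are the unit-norm
#' right singular vectors; variance explained is the squared singular values
#' over their total.  Component signs follow the same
#' largest-magnitude-loading-positive convention as [pca_genotypes()].
#'
#' @param traits a complete [trait_matrix()] (no missing cells; run
#'   [impute_regularized_pca()] first).
#' @return object of class `trait_pca_result`: `scores` (lines x components),
#'   `loadings` (traits x components), `varexp`, `line_ids`, `traits`,
#'   `imputation` (metadata carried over, or `NULL`).
#' @export
pca_traits <- function(traits) {
  stopifnot(inherits(traits, "trait_matrix"))
  X <- traits$values
  if (anyNA(X)) stop("trait matrix has missing cells; impute first")
  s <- apply(X, 2, stats::sd)
  if (any(s == 0))
    stop("zero-variance trait(s): ",
         paste(colnames(X)[s == 0], collapse = ", "))
  Xs <- scale(X)
  sv <- svd(Xs)
  k <- sum(sv$d > sv$d[1] * 1e-12)
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  scores <- sweep(U, 2, d, "*")
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(k)))
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = V,
                 varexp = sv$d^2 / sum(sv$d^2),
                 line_ids = rownames(X), traits = colnames(X),
                 imputation = attr(traits, "imputation")),
            class = c("trait_pca_result", "pca_result"))
}

#' Welch t-test of a trait PC projection between karyotype groups
#'
#' Compares component scores of INV-homozygous and STD-homozygous lines with
#' an unequal-variance (Welch) two-sample t-test; degrees of freedom follow
#' Welch-Satterthwaite and are generally non-integer.
#'
#' @param pca a `trait_pca_result` (or any object with `scores`/`line_ids`).
#' @param karyotypes a [karyotype_table()].
#' @param inversion inversion name.
#' @param component component index (default 1).
#' @return object of class `pc_ttest`: `component`, `inversion`, `t`, `df`,
#'   `p`, `mean_inv`, `mean_std`, `se_inv`, `se_std`, `n_inv`, `n_std`.
#' @export
pc_karyotype_ttest <- function(pca, karyotypes, inversion, component = 1L) {
  stopifnot(inherits(karyotypes, "karyotype_table"))
  score <- pca$scores[, component]
  kary <- karyotypes$call[match(pca$line_ids, karyotypes$line_ids), inversion]
  a <- score[!is.na(kary) & kary == "INV"]
  b <- score[!is.na(kary) & kary == "STD"]
  if (length(a) < 2 || length(b) < 2)
    stop("need >= 2 homozygous lines per class")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("degenerate group variances")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(component = component, inversion = inversion,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 mean_inv = mean(a), mean_std = mean(b),
                 se_inv = stats::sd(a) / sqrt(length(a)),
                 se_std = stats::sd(b) / sqrt(length(b)),
                 n_inv = length(a), n_std = length(b)),
            class = "pc_ttest")
}

#' Select the inversion-associated trait set for trait PCA
#'
#' A trait enters the PCA set for an inversion when (i) its matched-null
#' analysis flagged it as inversion-associated and (ii) at least
#' `min_hom_frac` of the lines with a karyotype call are homozygous for the
#' inverted arrangement (inversions rarer than that give too few INV lines
#' for stable projections).
#'
#' @param assoc data.frame with columns `trait`, `inversion`,
#'   `flagged_associated` (e.g. rows built from [matched_null()] results).
#' @param karyotypes a [karyotype_table()].
#' @param inversion inversion name.
#' @param min_hom_frac minimum homozygous-INV fraction (default 0.05).
#' @return character vector of trait names (possibly empty).
#' @export
select_inversion_traits <- function(assoc, karyotypes, inversion,
                                    min_hom_frac = 0.05) {
  kary <- karyotypes$call[, inversion]
  called <- !is.na(kary)
  if (!any(called) || mean(kary[called] == "INV") < min_hom_frac)
    return(character(0))
  rows <- assoc$inversion == inversion & assoc$flagged_associated
  unique(assoc$trait[rows & !is.na(rows)])
}
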