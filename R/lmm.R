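## Single-random-effect linear mixed model: exact REML via one-time
## eigendecomposition of the relatedness matrix and 1-D optimization over the
## variance ratio, plus the variant-wise score test.

#' Eigendecomposition of a relatedness matrix
#'
#' Computed once per GRM and reused across traits and permutations.
#' Relatedness matrices built with pairwise exclusion of missing genotypes
#' (the GCTA recipe) are mildly indefinite when missingness is appreciable;
#' as is standard for mixed-model software, small negative eigenvalues
#' within `psd_tol * trace / n` of zero are clamped ("bent") to zero, while
#' a matrix indefinite beyond that tolerance raises an error.  The negative
#' eigenvalues scale with the ratio of lines to variants, so sub-GRMs built
#' from modest variant counts need a proportionally larger tolerance.
#'
#' @param grm a [relatedness_matrix()] or plain symmetric matrix.
#' @param psd_tol relative tolerance for negative eigenvalues
#'   (default 0.25 of the mean diagonal).
#' @return list with `U` (eigenvectors), `d` (eigenvalues, non-increasing,
#'   clamped at 0) and `line_ids`.
#' @export
grm_eigen <- function(grm, psd_tol = 0.25) {
  K <- if (inherits(grm, "relatedness_matrix")) grm$K else grm
  e <- eigen(K, symmetric = TRUE)
  tol <- psd_tol * sum(diag(K)) / nrow(K)
  if (min(e$values) < -tol)
    stop("K is not positive semidefinite (min eigenvalue ",
         signif(min(e$values), 3), ")")
  list(U = e$vectors, d = pmax(e$values, 0), line_ids = rownames(K))
}

#' Fit the null mixed model by exact REML
#'
#' Model: `y = X beta + b + e`, `b ~ N(0, tau_g K)`, `e ~ N(0, tau_e I)`.
#' Writing `h = tau_g / tau_e`, the restricted likelihood is profiled over
#' `h` in the eigenbasis of K, where `V = tau_e (h D + I)` is diagonal; the
#' 1-D profile is maximized by a grid scan refined with [stats::optimize()],
#' and the boundary `h = 0` (no genetic variance) is always evaluated and
#' permitted.  This is exact for a single random effect — no iterative
#' REML with convergence tuning is involved.
#'
#' @param y named numeric vector of trait line means (complete; no NA).
#' @param K a [relatedness_matrix()] covering the lines in `y`.
#' @param covariates optional numeric matrix (lines x q) of fixed-effect
#'   covariates (an intercept is always added); rownames = line ids.
#' @param eig optional precomputed [grm_eigen()] of `K` (must match the line
#'   set of `y` exactly) — pass it when fitting many traits or permutations
#'   on one GRM.
#' @param h_grid_points number of points in the initial `log10(h)` scan.
#' @return object of class `null_model_fit` with variance components
#'   `tau_g`, `tau_e`, fixed effects `beta`, the restricted log-likelihood
#'   `reml_ll`, and cached projection quantities used by [score_test()].
#' @export
fit_null_lmm <- function(y, K, covariates = NULL, eig = NULL,
                         h_grid_points = 41L) {
  stopifnot(!is.null(names(y)), !anyNA(y))
  ids <- names(y)
  if (is.null(eig)) {
    Kin <- if (inherits(K, "relatedness_matrix")) K$K else K
    if (!all(ids %in% rownames(Kin)))
      stop("K does not cover all lines in y")
    eig <- grm_eigen(Kin[ids, ids])
  } else if (!identical(eig$line_ids, ids))
    stop("precomputed eig line set does not match y")
  n <- length(y)
  X <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) {
    cov <- as.matrix(covariates)
    if (!is.null(rownames(cov))) cov <- cov[ids, , drop = FALSE]
    X <- cbind(X, cov)
  }
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design")
  p <- ncol(X)
  U <- eig$U; d <- eig$d
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  neg_reml <- function(log10h) {
    h <- 10^log10h
    w <- 1 / (h * d + 1)
    A <- crossprod(Xt, w * Xt)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xt, w * yt)))
    r <- yt - drop(Xt %*% beta)
    rss <- sum(w * r^2)
    tau_e <- rss / (n - p)
    0.5 * ((n - p) * log(tau_e) + (n - p) + sum(log(h * d + 1)) +
             2 * sum(log(diag(ch))))
  }
  grid <- seq(-8, 8, length.out = h_grid_points)
  vals <- vapply(grid, neg_reml, numeric(1))
  j <- which.min(vals)
  lo <- grid[max(1, j - 1)]; hi <- grid[min(length(grid), j + 1)]
  opt <- stats::optimize(neg_reml, c(lo, hi), tol = 1e-8)
  # boundary h = 0 (pure OLS) always considered
  A0 <- crossprod(Xt, Xt)
  beta0 <- solve(A0, crossprod(Xt, yt))
  rss0 <- sum((yt - drop(Xt %*% beta0))^2)
  nll0 <- 0.5 * ((n - p) * log(rss0 / (n - p)) + (n - p) +
                   determinant(A0)$modulus[1])
  if (nll0 <= opt$objective) {
    h <- 0; nll <- nll0
  } else {
    h <- 10^opt$minimum; nll <- opt$objective
  }
  w <- 1 / (h * d + 1)
  A <- crossprod(Xt, w * Xt)
  beta <- drop(solve(A, crossprod(Xt, w * yt)))
  names(beta) <- colnames(X)
  r <- yt - drop(Xt %*% beta)
  tau_e <- sum(w * r^2) / (n - p)
  tau_g <- h * tau_e
  structure(list(line_ids = ids, n = n, p = p, beta = beta,
                 tau_g = tau_g, tau_e = tau_e, h = h, reml_ll = -nll,
                 boundary = h == 0,
                 U = U, d = d, w = w, yt = yt, Xt = Xt,
                 resid_t = r,                     # eigenbasis GLS residuals
                 Ainv_v = solve(A / tau_e),       # (X' V^-1 X)^-1
                 Py = drop(U %*% (w * r)) / tau_e),
            class = "null_model_fit")
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat("null_model_fit: n =", x$n, " tau_g =", signif(x$tau_g, 4),
      " tau_e =", signif(x$tau_e, 4),
      if (x$boundary) " (boundary: tau_g = 0)", "\n")
  invisible(x)
}

#' Variant-wise score test against a fitted null mixed model
#'
#' For each variant dosage vector `g`, the score statistic is
#' `T = (g' P y)^2 / (g' P g)` with `P` the REML projection under the fitted
#' covariance; `T` is chi-squared with 1 df under the null.  Variants are
#' filtered on the included lines to MAF >= `maf_min` and missing rate
#' <= `missing_max`; missing dosages are mean-imputed.  The effect
#' approximation `beta = g'Py / g'Pg` and `se = (g'Pg)^(-1/2)` are returned
#' for downstream colocalization.
#'
#' @param fit a [fit_null_lmm()] result.
#' @param G dosage matrix (lines x variants, rownames = line ids) or a
#'   single named vector.
#' @param maf_min,missing_max score-stage variant filters (defaults 0.05 and
#'   0.15; boundary values pass).
#' @return data.frame with one row per input variant: `id`, `n_used`, `maf`,
#'   `missing_rate`, `score`, `p`, `beta`, `se`, `skipped` (NA or a reason;
#'   skipped variants have NA statistics).
#' @export
score_test <- function(fit, G, maf_min = 0.05, missing_max = 0.15) {
  stopifnot(inherits(fit, "null_model_fit"))
  if (is.null(dim(G))) G <- matrix(G, ncol = 1,
                                   dimnames = list(names(G), "g"))
  G <- G[fit$line_ids, , drop = FALSE]
  n_obs <- colSums(!is.na(G))
  pfreq <- colSums(G, na.rm = TRUE) / (2 * n_obs)
  maf <- pmin(pfreq, 1 - pfreq)
  miss <- colSums(is.na(G)) / fit$n
  out <- data.frame(id = colnames(G), n_used = n_obs, maf = maf,
                    missing_rate = miss, score = NA_real_, p = NA_real_,
                    beta = NA_real_, se = NA_real_,
                    skipped = NA_character_, stringsAsFactors = FALSE,
                    row.names = NULL)
  out$skipped[!is.finite(maf) | maf < maf_min] <- "maf"
  out$skipped[miss > missing_max & is.na(out$skipped)] <- "missing"
  test <- which(is.na(out$skipped))
  if (length(test) == 0) return(out)
  Gt <- G[, test, drop = FALSE]
  mu <- 2 * pfreq[test]
  for (j in seq_along(test)) Gt[is.na(Gt[, j]), j] <- mu[j]
  Ge <- crossprod(fit$U, Gt)              # eigenbasis
  wG <- fit$w * Ge
  gPy <- drop(crossprod(Ge, fit$w * fit$resid_t)) / fit$tau_e
  C <- crossprod(fit$Xt, wG) / fit$tau_e  # X' V^-1 g, p x m
  gVg <- colSums(Ge * wG) / fit$tau_e
  gPg <- gVg - colSums(C * (fit$Ainv_v %*% C))
  const <- gPg <= 1e-10 * pmax(gVg, 1e-300)
  ok <- test[!const]
  out$skipped[test[const]] <- "constant"
  if (length(ok)) {
    sel <- !const
    out$score[ok] <- gPy[sel]^2 / gPg[sel]
    out$p[ok] <- stats::pchisq(out$score[ok], 1, lower.tail = FALSE)
    out$beta[ok] <- gPy[sel] / gPg[sel]
    out$se[ok] <- 1 / sqrt(gPg[sel])
  }
  out
}
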