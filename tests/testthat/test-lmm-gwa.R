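# The REML mixed model, the score test, residualization, and the GWA driver.

# an identity GRM over given ids
identity_grm <- function(ids) {
  K <- diag(length(ids))
  dimnames(K) <- list(ids, ids)
  relatedness_matrix(K, "vanraden_full")
}

test_that("with K = I the mixed model reduces to OLS", {
  set.seed(31)
  n <- 60
  ids <- sprintf("L%02d", 1:n)
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n)
  names(y) <- ids
  X <- matrix(x, ncol = 1, dimnames = list(ids, "x"))
  fit <- fit_null_lmm(y, identity_grm(ids), covariates = X)
  ols <- lm(y ~ x)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
  # total variance equals the REML residual variance; the split between
  # tau_g and tau_e is unidentifiable at K = I
  expect_equal(fit$tau_g + fit$tau_e, summary(ols)$sigma^2, tolerance = 1e-4)
  # residuals orthogonal to the fixed effects under the V^-1 inner product
  expect_lt(max(abs(crossprod(fit$Xt, fit$w * fit$resid_t))), 1e-6)
})

test_that("score test p-values track the OLS test at K = I", {
  set.seed(32)
  n <- 200; m <- 150
  ids <- sprintf("L%03d", 1:n)
  G <- matrix(rbinom(n * m, 2, rep(runif(m, 0.1, 0.5), each = n)), n,
              dimnames = list(ids, paste0("v", 1:m)))
  y <- rnorm(n)
  names(y) <- ids
  fit <- fit_null_lmm(y, identity_grm(ids))
  sc <- score_test(fit, G, maf_min = 0, missing_max = 1)
  p_ols <- apply(G, 2, function(g) summary(lm(y ~ g))$coefficients[2, 4])
  ok <- !is.na(sc$p)
  expect_gt(cor(sc$p[ok], p_ols[ok]), 0.999)
  # and when the fit is at the boundary (tau_g = 0) the score statistic
  # has its exact OLS closed form
  if (fit$h == 0) {
    g <- G[, 1] - mean(G[, 1])
    my <- y - mean(y)
    sigma2 <- sum(my^2) / (n - 1)
    T_ols <- sum(g * my)^2 / (sigma2 * sum(g^2))
    expect_equal(sc$score[1], T_ols, tolerance = 1e-10)
  }
})

test_that("the REML optimum beats a dense grid over the variance ratio", {
  sim <- small_sim()
  grm <- grm_vanraden(select_variants(sim$panel, "full"))
  tm <- simulate_traits(sim$panel, sim$karyotypes, sim$covariates,
                        trait_sim_config(n_traits = 1, r2_inv = 0.2,
                                         trait_missing = 0, seed = 12))
  y <- tm$values[, 1]; names(y) <- tm$line_ids
  fit <- fit_null_lmm(y, grm)
  # independent profile-REML evaluation on a 50-point grid
  eig <- grm_eigen(grm$K)
  yt <- drop(crossprod(eig$U, y)); Xt <- crossprod(eig$U, rep(1, fit$n))
  reml_at <- function(h) {
    w <- 1 / (h * eig$d + 1)
    A <- crossprod(Xt, w * Xt)
    beta <- solve(A, crossprod(Xt, w * yt))
    r <- yt - drop(Xt %*% beta)
    tau_e <- sum(w * r^2) / (fit$n - 1)
    -0.5 * ((fit$n - 1) * log(tau_e) + (fit$n - 1) + sum(log(h * eig$d + 1)) +
              determinant(A)$modulus[1])
  }
  grid_ll <- vapply(c(0, 10^seq(-6, 6, length.out = 49)), reml_at, numeric(1))
  expect_gte(fit$reml_ll, max(grid_ll) - 1e-6)
})

test_that("the score statistic is invariant to affine rescaling of the trait", {
  sim <- small_sim()
  grm <- grm_vanraden(select_variants(sim$panel, "full"))
  tm <- simulate_traits(sim$panel, sim$karyotypes, sim$covariates,
                        trait_sim_config(n_traits = 1, trait_missing = 0,
                                         seed = 8))
  y <- tm$values[, 1]; names(y) <- tm$line_ids
  G <- sim$panel$dosage[, 1:40]
  s1 <- score_test(fit_null_lmm(y, grm), G)
  y2 <- 3.7 * y - 11
  s2 <- score_test(fit_null_lmm(y2, grm), G)
  expect_equal(s1$score, s2$score, tolerance = 1e-6)
  # constant variants are skipped with a reason
  Gc <- cbind(G, const = rep(2, nrow(G)))
  s3 <- score_test(fit_null_lmm(y, grm), Gc, maf_min = 0)
  expect_equal(s3$skipped[ncol(Gc)], "constant")
})

test_that("residualizing on karyotype removes exactly the inversion signal", {
  sim <- small_sim()
  kary <- sim$karyotypes$call[, 1]
  ids <- sim$panel$line_ids
  # trait that is exactly c * I(INV): residuals collapse to zero
  y <- 2.5 * as.numeric(kary == "INV")
  names(y) <- ids
  res <- factored_out_residuals(y, sim$karyotypes)
  expect_equal(unname(res), rep(0, length(res)), tolerance = 1e-10)
  # trait orthogonal to karyotype: residuals are the centered trait
  set.seed(3)
  y2 <- rnorm(length(ids)); names(y2) <- ids
  y2 <- y2 - fitted(lm(y2 ~ kary)) + mean(y2)  # force exact orthogonality
  res2 <- factored_out_residuals(y2, sim$karyotypes)
  expect_equal(unname(res2), unname(y2 - mean(y2)), tolerance = 1e-10)
})

test_that("factored-out scoring flattens inside-inversion signal that LOCO keeps", {
  sim <- small_sim()
  grms <- cached("small_grms", build_grms(sim$panel))
  tm <- simulate_traits(sim$panel, sim$karyotypes, sim$covariates,
                        trait_sim_config(n_traits = 1, r2_inv = 0.2,
                                         trait_missing = 0, seed = 21))
  loco <- run_gwa(tm, sim$panel, sim$karyotypes, sim$covariates,
                  method = "loco", grms = grms, n_perm = 0, seed = 1)[[1]]
  fo <- run_gwa(tm, sim$panel, sim$karyotypes, sim$covariates,
                method = "factored_out", grms = grms, n_perm = 0,
                seed = 1)[[1]]
  reg <- classify_region(loco$results$arm, loco$results$pos, sim$inversions)
  inside <- reg == "inside" & !is.na(loco$results$score)
  expect_gt(mean(loco$results$score[inside]),
            5 * mean(fo$results$score[inside], na.rm = TRUE))
  # the factored-out inside-region signal sits at null level (mean chi2 ~ 1)
  expect_lt(mean(fo$results$score[inside], na.rm = TRUE), 2)
})

test_that("permutation replicates are reproducible and optional", {
  sim <- small_sim()
  grms <- cached("small_grms", build_grms(sim$panel))
  tm <- simulate_traits(sim$panel, sim$karyotypes, sim$covariates,
                        trait_sim_config(n_traits = 1, trait_missing = 0,
                                         seed = 31))
  r1 <- run_gwa(tm, sim$panel, sim$karyotypes, sim$covariates,
                method = "full", grms = grms, n_perm = 5, seed = 99)[[1]]
  r2 <- run_gwa(tm, sim$panel, sim$karyotypes, sim$covariates,
                method = "full", grms = grms, n_perm = 5, seed = 99)[[1]]
  expect_identical(r1$perm_p, r2$perm_p)
  expect_identical(r1$results, r2$results)
  r0 <- run_gwa(tm, sim$panel, sim$karyotypes, sim$covariates,
                method = "full", grms = grms, n_perm = 0, seed = 99)[[1]]
  expect_null(r0$perm_p)
  # observed and permuted runs share the variant universe
  expect_identical(rownames(r1$perm_p), r1$results$id)
})

test_that("variance components are recovered on a structured GRM", {
  sim <- small_sim()
  grm <- grm_vanraden(select_variants(sim$panel, "full"))
  eig <- grm_eigen(grm$K)
  n <- length(eig$line_ids)
  ratios <- vapply(1:40, function(r) {
    y <- with_seed(child_seed(1234, "vc", r), {
      b <- drop(eig$U %*% (sqrt(eig$d) * rnorm(n)))   # tau_g = 1
      b + rnorm(n)                                     # tau_e = 1
    })
    names(y) <- eig$line_ids
    fit <- fit_null_lmm(y, grm, eig = eig)
    fit$tau_g / fit$tau_e
  }, numeric(1))
  expect_lt(abs(median(ratios) - 1), 0.35)
})
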