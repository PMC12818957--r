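# Inversion-trait linear models, the matched-frequency polymorphism null,
# and the ancestry model comparisons.

test_that("the inversion lm matches a hand ANOVA decomposition", {
  ids <- sprintf("L%02d", 1:12)
  kt <- toy_karyotypes(ids, ids[1:5])
  y <- c(4.1, 3.8, 4.5, 4.0, 4.3,          # INV
         3.1, 2.9, 3.4, 3.0, 3.3, 2.8, 3.2) # STD
  names(y) <- ids
  fit <- inversion_trait_lm(y, kt, "In(2L)t", trait = "toy")
  ssb <- 5 * (mean(y[1:5]) - mean(y))^2 + 7 * (mean(y[6:12]) - mean(y))^2
  ssw <- sum((y[1:5] - mean(y[1:5]))^2) + sum((y[6:12] - mean(y[6:12]))^2)
  expect_equal(fit$f, (ssb / 1) / (ssw / 10))
  expect_equal(fit$r2, ssb / (ssb + ssw))
  expect_equal(fit$beta, mean(y[1:5]) - mean(y[6:12]))
  expect_equal(fit$n, 12)
  # degenerate cases
  y1 <- rep(2.5, 12); names(y1) <- ids
  f1 <- inversion_trait_lm(y1, kt, "In(2L)t")
  expect_equal(f1$r2, 0)
  expect_equal(f1$p, 1)
  y2 <- c(rep(1, 5), rep(0, 7)); names(y2) <- ids
  expect_equal(inversion_trait_lm(y2, kt, "In(2L)t")$r2, 1)
  # HET lines and missing karyotypes are excluded
  call3 <- kt$call; call3[12, 1] <- "HET"; call3[11, 1] <- NA
  expect_equal(inversion_trait_lm(y, karyotype_table(call3), "In(2L)t")$n, 10)
  expect_error(inversion_trait_lm(y[1:6], toy_karyotypes(ids[1:6], ids[6]),
                                  "In(2L)t"), ">= 2 homozygous")
})

test_that("matched variants satisfy the arm, frequency and distance rules", {
  sim <- small_sim()
  tm <- simulate_traits(sim$panel, sim$karyotypes, sim$covariates,
                        trait_sim_config(n_traits = 1, r2_inv = 0.15,
                                         trait_missing = 0, seed = 5))
  y <- tm$values[, 1]; names(y) <- tm$line_ids
  mn <- suppressWarnings(
    matched_null(y, sim$karyotypes, "In(2L)t", sim$panel, sim$inversions,
                 n_draws = 50, freq_tol = 0.05, seed = 2, trait = "t1"))
  v <- sim$panel$variants[match(mn$variant_ids, sim$panel$variants$id), ]
  expect_true(all(v$arm == "2L"))
  d <- pmin(abs(v$pos - sim$inversions$start), abs(v$pos - sim$inversions$end))
  inside <- v$pos >= sim$inversions$start & v$pos <= sim$inversions$end
  expect_true(all(!inside & d > 2e6))
  f_fold <- min(mn$inv_freq, 1 - mn$inv_freq)
  expect_true(all(abs(v$maf - f_fold) <= 0.05))
  expect_error(
    matched_null(y, sim$karyotypes, "In(2L)t", sim$panel, sim$inversions,
                 freq_tol = 1e-9, seed = 2),
    "empty matched-variant pool")
})

test_that("a null copied into every matched variant cannot be exceeded", {
  # panel whose eligible pool variants are exact copies of the inversion
  # indicator: observed R2 equals every null R2, so exceeds_null is FALSE
  n <- 40
  ids <- sprintf("L%02d", 1:n)
  inv_ids <- ids[1:14]
  kt <- toy_karyotypes(ids, inv_ids, name = "inv1")
  g <- 2 * as.numeric(ids %in% inv_ids)
  pos <- as.integer(c(4e6, 9e6, 9.1e6, 9.2e6, 9.3e6))  # inv at 1-2 Mb
  dos <- matrix(rep(g, length(pos)), ncol = length(pos),
                dimnames = list(ids, NULL))
  pan <- genotype_panel(dos, data.frame(
    id = paste0("2L_", pos, "_A_T"), arm = "2L", pos = pos,
    ref = "A", alt = "T", stringsAsFactors = FALSE))
  invs <- inversion_def("inv1", "2L", 1000000L, 2000000L)
  set.seed(1)
  y <- g / 2 + rnorm(n, sd = 0.5)
  names(y) <- ids
  mn <- suppressWarnings(
    matched_null(y, kt, "inv1", pan, invs, n_draws = 30, freq_tol = 0.5,
                 seed = 3))
  expect_true(all(abs(mn$null_r2 - mn$observed$r2) < 1e-12))
  expect_false(mn$exceeds_null)
  expect_false(mn$flagged_associated)
})

test_that("noise traits are flagged at no more than the nominal rate", {
  sim <- small_sim()
  tm <- simulate_traits(sim$panel, sim$karyotypes, sim$covariates,
                        trait_sim_config(n_traits = 150, r2_inv = 0,
                                         n_poly = 0, wolbachia_effect = 0,
                                         trait_missing = 0, seed = 77))
  flags <- vapply(tm$traits, function(tr) {
    y <- tm$values[, tr]; names(y) <- tm$line_ids
    suppressWarnings(
      matched_null(y, sim$karyotypes, "In(2L)t", sim$panel, sim$inversions,
                   n_draws = 60, freq_tol = 0.05,
                   seed = child_seed(5, tr))$flagged_associated)
  }, logical(1))
  # conjunction of p < 0.05 and exceeding the null: bounded by 0.05 plus
  # binomial noise
  expect_lte(mean(flags), 0.05 + 2 * sqrt(0.05 * 0.95 / length(flags)))
})

test_that("ancestry models recover their generative structure", {
  sim <- small_sim()
  ids <- sim$panel$line_ids
  kary <- sim$karyotypes$call[, 1]
  anc <- sim$covariates$ancestry_african
  # trait driven by karyotype only; ancestry uncorrelated by construction
  set.seed(9)
  y <- as.numeric(kary == "INV") * 1.5 + rnorm(length(ids), sd = 0.8)
  names(y) <- ids
  tab <- ancestry_models(y, sim$karyotypes, sim$covariates, "In(2L)t",
                         n_perm = 60, seed = 4)$models
  expect_lt(tab$p[tab$model == "full_vs_ancestry"], 0.01)
  expect_gt(tab$p[tab$model == "full_vs_inversion"], 0.05)
  expect_true(tab$exceeds_95[tab$model == "inversion_only"])
  # trait equal to a multiple of ancestry: ancestry-only R2 = 1
  y2 <- 3 * anc; names(y2) <- ids
  tab2 <- ancestry_models(y2, sim$karyotypes, sim$covariates, "In(2L)t",
                          n_perm = 0, seed = 1)$models
  expect_equal(tab2$r2[tab2$model == "ancestry_only"], 1)
  # Full model R2 >= each component model R2
  expect_gte(tab$r2[tab$model == "full"],
             max(tab$r2[tab$model %in% c("ancestry_only", "inversion_only")]))
})

test_that("R2 of the two-group lm equals the squared point-biserial correlation", {
  sim <- small_sim()
  tm <- simulate_traits(sim$panel, sim$karyotypes, sim$covariates,
                        trait_sim_config(n_traits = 5, r2_inv = 0.1,
                                         trait_missing = 0, seed = 55))
  kary <- sim$karyotypes$call[, 1]
  for (tr in tm$traits) {
    y <- tm$values[, tr]; names(y) <- tm$line_ids
    fit <- inversion_trait_lm(y, sim$karyotypes, "In(2L)t")
    expect_equal(fit$r2, cor(y, as.numeric(kary == "INV"))^2)
  }
})
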