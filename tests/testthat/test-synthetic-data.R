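# The panel/trait/candidate generators: determinism, tagging structure,
# frequency spectra and the controlled inversion variance share.

test_that("a fixed seed reproduces the simulation bit for bit", {
  cfg <- sim_config(n_lines = 40, n_variants = 60,
                    genome = c("2L" = 20e6),
                    inversions = inversion_def("inv1", "2L", 3e6, 12e6),
                    seed = 11)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$panel$dosage, b$panel$dosage)
  expect_identical(a$karyotypes$call, b$karyotypes$call)
  expect_identical(a$covariates, b$covariates)
  ta <- simulate_traits(a$panel, a$karyotypes, a$covariates,
                        trait_sim_config(n_traits = 3, seed = 11))
  tb <- simulate_traits(b$panel, b$karyotypes, b$covariates,
                        trait_sim_config(n_traits = 3, seed = 11))
  expect_identical(ta$values, tb$values)
  # child streams are independent: genotype draws unchanged by seed label
  expect_false(identical(
    simulate_panel(sim_config(n_lines = 40, n_variants = 60,
                              genome = c("2L" = 20e6),
                              inversions = inversion_def("inv1", "2L",
                                                         3e6, 12e6),
                              seed = 12))$panel$dosage,
    a$panel$dosage))
})

test_that("inversion frequency 0 gives an all-STD panel and degrades traits", {
  cfg <- sim_config(n_lines = 30, n_variants = 40, genome = c("2L" = 20e6),
                    inversions = inversion_def("inv1", "2L", 3e6, 12e6),
                    inv_freq = 0, seed = 3)
  sim <- suppressWarnings(simulate_panel(cfg))
  expect_true(all(sim$karyotypes$call == "STD"))
  expect_warning(simulate_panel(cfg), "degenerate")
  expect_error(
    simulate_traits(sim$panel, sim$karyotypes, sim$covariates,
                    trait_sim_config(n_traits = 1, r2_inv = 0.1, seed = 1)),
    "no variance")
})

test_that("perfect tagging makes inside variants copies of the karyotype", {
  cfg <- sim_config(n_lines = 60, n_variants = 80, genome = c("2L" = 20e6),
                    inversions = inversion_def("inv1", "2L", 3e6, 12e6),
                    leak0 = 0, leak_length = Inf, missing_rate = 0, seed = 5)
  sim <- simulate_panel(cfg)
  kary <- as.numeric(sim$karyotypes$call[, 1] == "INV")
  inside <- sim$panel$variants$pos >= 3e6 & sim$panel$variants$pos <= 12e6
  r2 <- apply(sim$panel$dosage[, inside, drop = FALSE], 2,
              function(g) cor(g, kary)^2)
  expect_true(all(r2 > 1 - 1e-12))
})

test_that("tagging r-squared decays with distance from the breakpoints", {
  cfg <- sim_config(n_lines = 200, n_variants = 2000,
                    genome = c("2L" = 23e6),
                    inversions = inversion_def("inv1", "2L", 6e6, 14e6),
                    leak0 = 0.02, leak_length = 4e6, missing_rate = 0,
                    seed = 17)
  sim <- simulate_panel(cfg)
  kary <- as.numeric(sim$karyotypes$call[, 1] == "INV")
  v <- sim$panel$variants
  d <- ifelse(v$pos >= 6e6 & v$pos <= 14e6, 0,
              pmin(abs(v$pos - 6e6), abs(v$pos - 14e6)))
  r2 <- suppressWarnings(
    apply(sim$panel$dosage, 2, function(g) cor(g, kary)^2))
  bins <- cut(d, c(-1, 1, 5e5, 1.2e6, 1.92e6), labels = FALSE)
  means <- tapply(r2, bins, mean, na.rm = TRUE)
  expect_true(all(diff(means) < 0))
})

test_that("outside-variant MAF matches the folded Beta spectrum", {
  a <- 0.8; b <- 3
  cfg <- sim_config(n_lines = 200, n_variants = c(0L, 5000L),
                    genome = c("2L" = 23e6, "2R" = 21e6),
                    inversions = inversion_def("inv1", "2L", 3e6, 12e6),
                    maf_beta = c(a, b), missing_rate = 0, seed = 23)
  # the only inversion lives on 2L, which carries no variants here;
  # every 2R variant draws its frequency from the Beta spectrum
  sim <- simulate_panel(cfg)
  oracle <- stats::integrate(function(p) pmin(p, 1 - p) * stats::dbeta(p, a, b),
                             0, 1)$value
  expect_equal(mean(sim$panel$variants$maf), oracle, tolerance = 0.03)
})

test_that("realized inversion frequency is binomially consistent with q", {
  sim <- small_sim()
  q <- 0.25; n <- 120
  n_inv <- sum(sim$karyotypes$call[, 1] == "INV")
  ci <- stats::qbinom(c(0.005, 0.995), n, q)
  expect_gte(n_inv, ci[1])
  expect_lte(n_inv, ci[2])
})

test_that("the inversion variance share hits its target in expectation", {
  sim <- small_sim()
  tm <- simulate_traits(sim$panel, sim$karyotypes, sim$covariates,
                        trait_sim_config(n_traits = 120, r2_inv = 0.10,
                                         trait_missing = 0, seed = 31))
  r2 <- vapply(tm$traits, function(tr) {
    y <- tm$values[, tr]; names(y) <- tm$line_ids
    inversion_trait_lm(y, sim$karyotypes, "In(2L)t")$r2
  }, numeric(1))
  expect_equal(mean(r2), 0.10, tolerance = 0.02)
  # near-deterministic limit: residual variance dominated by the inversion
  tm2 <- simulate_traits(sim$panel, sim$karyotypes, sim$covariates,
                         trait_sim_config(n_traits = 3, r2_inv = 0.99,
                                          trait_missing = 0, seed = 32))
  r2b <- vapply(tm2$traits, function(tr) {
    y <- tm2$values[, tr]; names(y) <- tm2$line_ids
    inversion_trait_lm(y, sim$karyotypes, "In(2L)t")$r2
  }, numeric(1))
  expect_true(all(r2b > 0.95))
})

test_that("null traits give uniform inversion-model p-values", {
  sim <- small_sim()
  tm <- simulate_traits(sim$panel, sim$karyotypes, sim$covariates,
                        trait_sim_config(n_traits = 200, r2_inv = 0,
                                         n_poly = 0, wolbachia_effect = 0,
                                         trait_missing = 0, seed = 41))
  p <- vapply(tm$traits, function(tr) {
    y <- tm$values[, tr]; names(y) <- tm$line_ids
    inversion_trait_lm(y, sim$karyotypes, "In(2L)t")$p
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.05)
})

test_that("candidate sets respect rate, enrichment and the flag contract", {
  sim <- small_sim()
  region <- sim$inversions[1, ]
  flat <- simulate_candidate_sets(sim$panel$variants, region,
                                  frac_outliers = 0.3,
                                  enrichment_factor = 1, seed = 7)
  expect_identical(flat$outlier, flat$empirical_p < 0.05)
  inside <- classify_region(sim$panel$variants$arm, sim$panel$variants$pos,
                            region, buffer_bp = 0) == "inside"
  expect_equal(mean(flat$outlier[inside]), mean(flat$outlier[!inside]),
               tolerance = 0.15)
  rich <- simulate_candidate_sets(sim$panel$variants, region,
                                  frac_outliers = 0.05,
                                  enrichment_factor = 10, seed = 7)
  tab <- table(inside, rich$outlier)
  or <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_gt(or, 3)
  none <- simulate_candidate_sets(sim$panel$variants, region,
                                  frac_outliers = 0, seed = 7)
  expect_equal(sum(none$outlier), 0)
})
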