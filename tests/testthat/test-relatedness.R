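# GRM construction (VanRaden, GCTA pairwise, LOCO) and LD pruning, against
# hand and loop oracles.

test_that("VanRaden GRM matches the hand-evaluated definition", {
  dos <- matrix(c(0, 2, 2,
                  2, 0, 2), nrow = 3,
                dimnames = list(c("L1", "L2", "L3"), NULL))
  p <- genotype_panel(dos, data.frame(id = c("v1", "v2"), arm = "2L",
                                      pos = c(1L, 2L), ref = "A", alt = "T"))
  K <- grm_vanraden(p)$K
  expect_equal(K["L1", "L1"], 2.5)
  expect_equal(K["L1", "L2"], -2.0)
  # full loop oracle
  pf <- colMeans(dos) / 2
  Z <- sweep(dos, 2, 2 * pf)
  expect_equal(K, tcrossprod(Z) / (2 * sum(pf * (1 - pf))))
  # identical dosage rows are fully related
  dos2 <- rbind(dos, L4 = dos["L3", ])
  p2 <- genotype_panel(dos2, p$variants[, 1:5])
  K2 <- grm_vanraden(p2)$K
  expect_equal(K2["L3", "L4"], K2["L3", "L3"])
  expect_equal(K2["L3", "L4"], K2["L4", "L4"])
})

test_that("VanRaden normalization gives diag ~1, off-diag ~0 for unrelated lines", {
  # Hardy-Weinberg dosages: the VanRaden denominator normalizes the expected
  # diagonal to 1 for outbred samples (inbred 0/2 panels sit near 2)
  set.seed(9)
  n <- 40; m <- 3000
  pvec <- runif(m, 0.1, 0.5)
  dos <- matrix(rbinom(n * m, 2, rep(pvec, each = n)),
                n, dimnames = list(sprintf("L%02d", 1:n), NULL))
  pan <- genotype_panel(dos, data.frame(id = paste0("v", 1:m), arm = "2L",
                                        pos = seq_len(m) * 1000L,
                                        ref = "A", alt = "T"))
  K <- grm_vanraden(filter_variants(pan, 0.05, 0.2))$K
  expect_equal(mean(diag(K)), 1, tolerance = 0.05)
  expect_equal(mean(K[upper.tri(K)]), 0, tolerance = 0.03)
})

test_that("GCTA GRM matches the per-variant standardized formula", {
  dos <- matrix(c(0, 2), nrow = 2, dimnames = list(c("L1", "L2"), NULL))
  p <- genotype_panel(dos, data.frame(id = "v1", arm = "2L", pos = 1L,
                                      ref = "A", alt = "T"))
  K <- grm_gcta(p)$K
  expect_equal(unname(K), rbind(c(2, -2), c(-2, 2)))
  # with no missingness, equals VanRaden-style product of standardized
  # columns divided by M
  set.seed(4)
  n <- 15; m <- 40
  dos <- matrix(2 * (runif(n * m) < rep(runif(m, 0.2, 0.5), each = n)), n,
                dimnames = list(sprintf("L%02d", 1:n), NULL))
  keep <- apply(dos, 2, function(g) length(unique(g)) > 1)
  dos <- dos[, keep]
  pan <- genotype_panel(dos, data.frame(id = paste0("v", seq_len(ncol(dos))),
                                        arm = "2L",
                                        pos = seq_len(ncol(dos)) * 100L,
                                        ref = "A", alt = "T"))
  pf <- colMeans(dos) / 2
  Z <- sweep(sweep(dos, 2, 2 * pf), 2, sqrt(2 * pf * (1 - pf)), "/")
  expect_equal(grm_gcta(pan)$K, tcrossprod(Z) / ncol(dos))
  expect_error(grm_gcta(genotype_panel(
    matrix(c(2, 2), 2, dimnames = list(c("L1", "L2"), NULL)),
    data.frame(id = "v", arm = "2L", pos = 1L, ref = "A", alt = "T"))),
    "monomorphic")
})

test_that("pairwise-M missingness handling matches a double-loop oracle", {
  set.seed(12)
  n <- 12; m <- 60
  dos <- matrix(2 * (runif(n * m) < rep(runif(m, 0.2, 0.5), each = n)), n,
                dimnames = list(sprintf("L%02d", 1:n), NULL))
  dos[cbind(sample(n, 15, TRUE), sample(m, 15, TRUE))] <- NA
  keep <- apply(dos, 2, function(g) length(unique(na.omit(g))) > 1 &&
                  sum(!is.na(g)) >= 2)
  dos <- dos[, keep]
  pan <- genotype_panel(dos, data.frame(id = paste0("v", seq_len(ncol(dos))),
                                        arm = "2L",
                                        pos = seq_len(ncol(dos)) * 100L,
                                        ref = "A", alt = "T"))
  K <- grm_gcta(pan)$K
  pf <- colSums(dos, na.rm = TRUE) / (2 * colSums(!is.na(dos)))
  Z <- sweep(sweep(dos, 2, 2 * pf), 2, sqrt(2 * pf * (1 - pf)), "/")
  oracle <- matrix(NA_real_, n, n)
  for (i in 1:n) for (k in 1:n) {
    ok <- !is.na(Z[i, ]) & !is.na(Z[k, ])
    oracle[i, k] <- sum(Z[i, ok] * Z[k, ok]) / sum(ok)
  }
  expect_equal(unname(K), (oracle + t(oracle)) / 2)
  # masking one more entry: the matrix still equals its loop oracle (the
  # variant's allele frequency is re-estimated, so the perturbation is not
  # confined to one line's row/column, but entries away from line 3 move
  # only through that frequency shift)
  dos2 <- dos
  dos2[3, 5] <- NA
  K2 <- grm_gcta(genotype_panel(dos2, pan$variants[, 1:5]))$K
  pf2 <- colSums(dos2, na.rm = TRUE) / (2 * colSums(!is.na(dos2)))
  Z2 <- sweep(sweep(dos2, 2, 2 * pf2), 2, sqrt(2 * pf2 * (1 - pf2)), "/")
  oracle2 <- matrix(NA_real_, n, n)
  for (i in 1:n) for (k in 1:n) {
    ok <- !is.na(Z2[i, ]) & !is.na(Z2[k, ])
    oracle2[i, k] <- sum(Z2[i, ok] * Z2[k, ok]) / sum(ok)
  }
  expect_equal(unname(K2), (oracle2 + t(oracle2)) / 2)
  off3 <- abs(K2 - K); off3[3, ] <- 0; off3[, 3] <- 0
  expect_lt(max(off3), max(abs((K2 - K)[3, ])))
})

test_that("LD pruning is greedy, windowed and deterministic", {
  mk <- function(pos, cols) {
    dos <- do.call(cbind, cols)
    dimnames(dos) <- list(sprintf("L%02d", seq_len(nrow(dos))),
                          paste0("v", seq_along(pos)))
    genotype_panel(dos, data.frame(id = paste0("v", seq_along(pos)),
                                   arm = "2L", pos = as.integer(pos),
                                   ref = "A", alt = "T"))
  }
  g <- rep(c(0, 2), 10)
  # identical variants 3 kb apart: second dropped; 6 kb apart: both kept
  expect_identical(ld_prune(mk(c(1000, 4000), list(g, g))), "v1")
  expect_identical(ld_prune(mk(c(1000, 7000), list(g, g))), c("v1", "v2"))
  # 50-variant panel vs exhaustive pairwise audit of the greedy invariants
  sim <- small_sim()
  pan <- invgwas:::panel_subset(sim$panel, variants = 1:50)
  kept <- ld_prune(pan, r2_max = 0.2, window_bp = 5000)
  v <- pan$variants
  kept_idx <- match(kept, v$id)
  r2 <- function(i, j) {
    r <- suppressWarnings(cor(pan$dosage[, i], pan$dosage[, j],
                              use = "pairwise.complete.obs"))
    if (is.na(r)) 0 else r^2
  }
  for (a in kept_idx) for (b in kept_idx)
    if (a < b && v$arm[a] == v$arm[b] && abs(v$pos[a] - v$pos[b]) <= 5000)
      expect_lte(r2(a, b), 0.2)
  for (dtied in setdiff(seq_len(50), kept_idx)) {
    earlier <- kept_idx[v$arm[kept_idx] == v$arm[dtied] &
                          v$pos[kept_idx] < v$pos[dtied] &
                          v$pos[dtied] - v$pos[kept_idx] <= 5000]
    expect_true(any(vapply(earlier, function(e) r2(e, dtied) > 0.2,
                           logical(1))))
  }
  expect_identical(ld_prune(pan), kept)  # deterministic rerun
})

test_that("LOCO sub-GRMs partition the pruned set and decorrelate the inversion", {
  sim <- small_sim()
  ld_panel <- select_variants(sim$panel, "ld")
  # excluding an arm with no variants reproduces the full GCTA GRM
  expect_equal(grm_loco(ld_panel, "X")$K,
               grm_gcta(ld_panel, drop_monomorphic = TRUE)$K)
  # each variant omitted exactly once across the arm exclusions
  arms <- unique(ld_panel$variants$arm)
  omitted <- unlist(lapply(arms, function(a)
    ld_panel$variants$id[ld_panel$variants$arm == a]))
  expect_setequal(omitted, ld_panel$variants$id)
  expect_equal(anyDuplicated(omitted), 0)

  # relatedness among INV/INV pairs: elevated in full, near zero in LOCO(2L)
  kary <- sim$karyotypes$call[, 1]
  full <- grm_vanraden(select_variants(sim$panel, "full"))
  loco <- grm_loco(ld_panel, "2L")
  rk_full <- relatedness_by_karyotype(full, sim$karyotypes, "In(2L)t")
  rk_loco <- relatedness_by_karyotype(loco, sim$karyotypes, "In(2L)t")
  inv_full <- rk_full$mean[rk_full$pair_class == "INV/INV"]
  inv_loco <- rk_loco$mean[rk_loco$pair_class == "INV/INV"]
  expect_gt(inv_full, inv_loco)
  expect_gt(inv_full, 0.1)
  expect_lt(abs(inv_loco), 0.1)
})

test_that("all GRM recipes are PSD on complete-genotype panels", {
  cfg <- sim_config(n_lines = 50, n_variants = 100,
                    genome = c("2L" = 23e6, "2R" = 21e6),
                    inversions = inversion_def("inv1", "2L", 3e6, 12e6),
                    missing_rate = 0, seed = 77)
  sim <- simulate_panel(cfg)
  for (K in list(grm_vanraden(select_variants(sim$panel, "full")),
                 grm_gcta(select_variants(sim$panel, "ld"),
                          drop_monomorphic = TRUE),
                 grm_loco(select_variants(sim$panel, "ld"), "2L"))) {
    ev <- eigen(K$K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * sum(diag(K$K)) / nrow(K$K))
    expect_equal(K$K, t(K$K))
  }
})

test_that("GRM TSV serialization round-trips", {
  sim <- small_sim()
  g <- grm_vanraden(select_variants(sim$panel, "full"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_grm(g, path)
  g2 <- read_grm(path)
  expect_equal(g2$K, g$K, tolerance = 1e-10)
})
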