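## End-to-end scenario driver: simulate -> filter -> GRMs -> PCAs ->
## inversion association -> GWA x methods -> summaries -> enrichment ->
## colocalization, with deterministic seeds and a provenance manifest.

#' Configuration for an end-to-end scenario run
#'
#' @param sim a [sim_config()].
#' @param trait_sim a [trait_sim_config()].
#' @param methods GWA strategies to run (default all four).
#' @param n_perm permutations per trait and method (default 25 for
#'   desk-scale runs; raise to 100 for full calibration).
#' @param n_gwa_traits number of traits carried into the GWA stage (default
#'   4; the inversion-association stage always uses all traits).
#' @param p_threshold GWA hit threshold (default 1e-5).
#' @param top_k top-hit count for enrichment (default 500).
#' @param window,step colocalization window/step in bp.
#' @param seed master seed; every stage derives child streams.
#' @param out_dir output directory for artifacts (created if needed).
#' @return a `run_config` list.
#' @export
run_config <- function(sim = sim_config(), trait_sim = trait_sim_config(),
                       methods = c("full", "ld", "loco", "factored_out"),
                       n_perm = 25L, n_gwa_traits = 4L, p_threshold = 1e-5,
                       top_k = 500L, window = 10000L, step = 5000L,
                       seed = 1L, out_dir = tempfile("invgwas_run_")) {
  methods <- match.arg(methods, c("full", "ld", "loco", "factored_out"),
                       several.ok = TRUE)
  structure(list(sim = sim, trait_sim = trait_sim, methods = methods,
                 n_perm = as.integer(n_perm),
                 n_gwa_traits = as.integer(n_gwa_traits),
                 p_threshold = p_threshold, top_k = as.integer(top_k),
                 window = as.integer(window), step = as.integer(step),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run a full scenario end to end
#'
#' Executes every stage of the pipeline on a simulated panel and writes all
#' artifacts (TSVs keyed by stage) plus a `provenance.json` manifest (config
#' and seeds) into `cfg$out_dir`.  Rerunning with the same config reproduces
#' every artifact bit for bit.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the in-memory stage outputs: `sim`,
#'   `grms`, `genotype_pca`, `pc_models`, `assoc`, `trait_pca`, `gwa`,
#'   `summaries`, `exceedance`, `enrichment`, `coloc`, and `out_dir`.
#' @export
run_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(cfg$out_dir)
  cfg$sim$seed <- child_seed(cfg$seed, "sim")
  cfg$trait_sim$seed <- child_seed(cfg$seed, "trait_sim")

  # provenance first, before any stochastic step
  prov <- list(package = "invgwas",
               version = as.character(utils::packageVersion("invgwas")),
               seed = cfg$seed,
               child_seeds = list(sim = cfg$sim$seed,
                                  trait_sim = cfg$trait_sim$seed),
               methods = cfg$methods, n_perm = cfg$n_perm,
               p_threshold = cfg$p_threshold, top_k = cfg$top_k,
               window = cfg$window, step = cfg$step)
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  stage <- function(name, expr) {
    message("[", format(Sys.time(), "%H:%M:%S"), "] ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  sim <- stage("simulate", simulate_panel(cfg$sim))
  traits <- stage("traits",
                  simulate_traits(sim$panel, sim$karyotypes, sim$covariates,
                                  cfg$trait_sim))
  write_genotypes(sim$panel, file.path(out, "genotypes.vcf"))
  write_karyotypes(sim$karyotypes, file.path(out, "karyotypes.tsv"))
  write_inversions(sim$inversions, file.path(out, "inversions.tsv"))
  write_traits(traits, file.path(out, "traits.tsv"))
  utils::write.table(sim$covariates, file.path(out, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  grms <- stage("grms", build_grms(sim$panel))
  write_grm(grms$full, file.path(out, "grm_full.tsv"))
  write_grm(grms$ld, file.path(out, "grm_ld.tsv"))

  inv1 <- sim$inversions$name[1]
  gpca <- stage("genotype_pca", {
    list(Full = pca_genotypes(select_variants(sim$panel, "full"),
                              n_components = 4, strategy = "Full"),
         LD = pca_genotypes(select_variants(sim$panel, "ld"),
                            n_components = 4, strategy = "LD"),
         LOCO = pca_genotypes(
           select_variants(sim$panel, "loco",
                           excluded_arm = sim$inversions$arm[1]),
           n_components = 4,
           strategy = paste0("LOCO(", sim$inversions$arm[1], ")")))
  })
  pc_models <- stage("pc_inversion_models", {
    lapply(gpca, function(p)
      pc_inversion_model(p, sim$karyotypes, inv1, component = 1,
                         n_perm = cfg$n_perm,
                         seed = child_seed(cfg$seed, "pc_model")))
  })
  pcm_tab <- do.call(rbind, lapply(names(pc_models), function(s) {
    m <- pc_models[[s]]
    data.frame(strategy = s, component = m$component, inversion = m$inversion,
               n = m$n, r2 = m$r2, f = m$f, p = m$p,
               exceeds_95 = m$exceeds_95, stringsAsFactors = FALSE)
  }))
  utils::write.table(pcm_tab, file.path(out, "pc_inversion_models.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  assoc <- stage("inversion_association", {
    rows <- lapply(traits$traits, function(tr) {
      y <- traits$values[, tr]; names(y) <- traits$line_ids
      mn <- matched_null(y, sim$karyotypes, inv1, sim$panel, sim$inversions,
                         n_draws = max(40L, cfg$n_perm * 4L),
                         seed = child_seed(cfg$seed, "matched", tr),
                         trait = tr)
      data.frame(trait = tr, inversion = inv1, n = mn$observed$n,
                 beta = mn$observed$beta, r2 = mn$observed$r2,
                 p = mn$observed$p, r2_q95 = mn$r2_q95,
                 significant = mn$significant,
                 exceeds_null = mn$exceeds_null,
                 flagged_associated = mn$flagged_associated,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  utils::write.table(assoc, file.path(out, "inversion_association.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tpca <- stage("trait_pca", {
    sel <- select_inversion_traits(assoc, sim$karyotypes, inv1)
    if (length(sel) >= 3) {
      sub <- trait_matrix(traits$values[, sel, drop = FALSE],
                          traits$category[match(sel, traits$traits)])
      completed <- impute_regularized_pca(sub, ncp = 2)
      p <- pca_traits(completed)
      tt <- pc_karyotype_ttest(p, sim$karyotypes, inv1, component = 1)
      list(selected = sel, pca = p, ttest = tt)
    } else list(selected = sel, pca = NULL, ttest = NULL)
  })
  if (!is.null(tpca$pca)) {
    utils::write.table(
      data.frame(line_id = tpca$pca$line_ids, tpca$pca$scores,
                 check.names = FALSE),
      file.path(out, "trait_pca_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(trait = rownames(tpca$pca$loadings), tpca$pca$loadings,
                 check.names = FALSE),
      file.path(out, "trait_pca_loadings.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  gwa_traits <- utils::head(traits$traits, cfg$n_gwa_traits)
  gwa_tm <- trait_matrix(traits$values[, gwa_traits, drop = FALSE],
                         traits$category[match(gwa_traits, traits$traits)])
  gwa <- stage("gwa", {
    res <- lapply(cfg$methods, function(m)
      run_gwa(gwa_tm, sim$panel, sim$karyotypes, sim$covariates,
              method = m, grms = grms, n_perm = cfg$n_perm,
              seed = child_seed(cfg$seed, "gwa", m)))
    names(res) <- cfg$methods
    res
  })
  for (m in names(gwa))
    for (r in gwa[[m]])
      write_gwa(r, file.path(out, sprintf("gwa_%s_%s.tsv", m, r$trait)))

  summaries <- stage("summaries", {
    lapply(gwa, function(runs) lapply(runs, function(r)
      summarize_bins(r, sim$inversions, cfg$p_threshold)))
  })
  exc <- stage("exceedance", {
    if (cfg$n_perm == 0) NULL
    else lapply(names(gwa), function(m) {
      do.call(rbind, lapply(gwa[[m]], function(r)
        suppressWarnings(exceedance(
          summarize_bins(r, sim$inversions, cfg$p_threshold),
          summarize_bins_perms(r, sim$inversions, cfg$p_threshold)))))
    })
  })
  if (!is.null(exc)) {
    names(exc) <- names(gwa)
    for (m in names(exc))
      utils::write.table(exc[[m]],
                         file.path(out, sprintf("exceedance_%s.tsv", m)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  enr <- stage("enrichment", {
    cand <- simulate_candidate_sets(
      sim$panel$variants, sim$inversions[1, ], frac_outliers = 0.05,
      enrichment_factor = 4,
      seed = child_seed(cfg$seed, "candidates"))
    write_candidates(cand, file.path(out, "candidates.tsv"))
    run1 <- gwa[[1]][[1]]
    universe <- run1$results$id[!is.na(run1$results$p)]
    k <- min(cfg$top_k, length(universe))
    obs <- enrichment_fet(top_hits(run1, k), cand, universe)
    perm_or <- if (cfg$n_perm > 0)
      vapply(seq_len(cfg$n_perm), function(r)
        enrichment_fet(top_hits(run1, k, p_override = run1$perm_p[, r]),
                       cand, universe)$odds_ratio, numeric(1))
    else numeric(0)
    list(candidates = cand, observed = obs, permuted_or = perm_or,
         exceedance = if (cfg$n_perm >= 20)
           enrichment_exceedance(obs$odds_ratio, perm_or) else NULL)
  })

  coloc <- stage("coloc", {
    if (is.null(tpca$pca) || ncol(tpca$pca$scores) < 2 ||
          !all(c("loco") %in% names(gwa))) NULL
    else {
      pc_tm <- trait_matrix(tpca$pca$scores[, 1:2],
                            c("other", "other"))
      pc_runs <- run_gwa(pc_tm, sim$panel, sim$karyotypes, sim$covariates,
                         method = "loco", grms = grms, n_perm = 0,
                         seed = child_seed(cfg$seed, "coloc"))
      cw <- sliding_coloc(pc_runs[[1]], pc_runs[[2]],
                          window = cfg$window, step = cfg$step)
      utils::write.table(cw, file.path(out, "coloc_windows.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cw
    }
  })

  invisible(list(sim = sim, traits = traits, grms = grms,
                 genotype_pca = gpca, pc_models = pc_models, assoc = assoc,
                 trait_pca = tpca, gwa = gwa, summaries = summaries,
                 exceedance = exc, enrichment = enr, coloc = coloc,
                 out_dir = out))
}
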