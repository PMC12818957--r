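## GWA orchestration: the four strategies (Full, LD, LOCO, Factored-out),
## inversion residualization, and per-trait permutation replicates.

#' Residualize a trait on inversion karyotypes ("Factored-out" pretreatment)
#'
#' Regresses the trait line means on the karyotypes of the listed inversions,
#' each entering as a categorical factor over its observed states
#' (STD/INV/HET), and returns the residuals to be used as the trait.  Lines
#' with a missing call for any listed inversion are dropped; collinear
#' factor levels are dropped by the least-squares fit with a message.
#'
#' @param trait_values named numeric vector of line means.
#' @param karyotypes a [karyotype_table()].
#' @param inversions inversion names to factor out (default: all columns of
#'   `karyotypes`).
#' @return named numeric residual vector over the retained lines.
#' @export
factored_out_residuals <- function(trait_values, karyotypes,
                                   inversions = NULL) {
  stopifnot(inherits(karyotypes, "karyotype_table"))
  if (is.null(inversions)) inversions <- karyotypes$inversions
  if (!all(inversions %in% karyotypes$inversions))
    stop("unknown inversion(s): ",
         paste(setdiff(inversions, karyotypes$inversions), collapse = ", "))
  calls <- karyotypes$call[match(names(trait_values), karyotypes$line_ids),
                           inversions, drop = FALSE]
  use <- !is.na(trait_values) & rowSums(is.na(calls)) == 0
  y <- trait_values[use]
  df <- as.data.frame(calls[use, , drop = FALSE], stringsAsFactors = FALSE)
  names(df) <- make.names(inversions)
  df <- as.data.frame(lapply(df, factor), stringsAsFactors = TRUE)
  keep <- vapply(df, function(f) nlevels(droplevels(f)) > 1, logical(1))
  if (!all(keep))
    message("dropping invariant karyotype factor(s): ",
            paste(inversions[!keep], collapse = ", "))
  if (!any(keep)) return(y - mean(y))
  X <- stats::model.matrix(~ ., df[, keep, drop = FALSE])
  fit <- stats::lm.fit(X, y)
  if (any(is.na(fit$coefficients)))
    message("collinear karyotype level(s) dropped from residualization")
  res <- fit$residuals
  names(res) <- names(y)
  res
}

#' Build the GRM family for all four GWA strategies
#'
#' @param panel a [genotype_panel()] (unfiltered; the per-recipe filters are
#'   applied here via [select_variants()]).
#' @param arms arms for which LOCO sub-GRMs are built (default: all arms
#'   present in the panel).
#' @return list with `full` (VanRaden), `ld` (GCTA, pruned), and `loco`
#'   (named list of per-arm exclusion GRMs).
#' @export
build_grms <- function(panel, arms = NULL) {
  if (is.null(arms)) arms <- unique(panel$variants$arm)
  ld_panel <- select_variants(panel, "ld")
  loco <- lapply(arms, function(a) grm_loco(ld_panel, a))
  names(loco) <- arms
  list(full = grm_vanraden(select_variants(panel, "full")),
       ld = grm_gcta(ld_panel, drop_monomorphic = TRUE),
       loco = loco)
}

#' Genome-wide association with permutations under one strategy
#'
#' For each trait, fits the null mixed model `y ~ Wolbachia + GRM` on the
#' lines with a non-missing trait value and scores every variant of the
#' panel with [score_test()] (full model `y ~ variant + Wolbachia + GRM`).
#' Strategies differ in the GRM and the trait pretreatment:
#' `full` uses the VanRaden full-genome GRM; `ld` the GCTA GRM on the pruned
#' set; `factored_out` the full GRM with the trait residualized on inversion
#' karyotypes ([factored_out_residuals()]); `loco` refits the null model per
#' chromosome arm with that arm's exclusion GRM and scores only that arm's
#' variants.  Heterozygous-karyotype lines are retained — the scan makes no
#' distinction between inverted and non-inverted regions or lines.
#'
#' Permutation replicates shuffle the trait values across the included lines
#' (covariates and GRM stay attached to their lines) and refit the null
#' model before re-scoring, each replicate under a child seed of `seed`.
#'
#' @param traits a [trait_matrix()] (or named numeric vector for one trait).
#' @param panel a [genotype_panel()]; variants are score-filtered per trait
#'   to MAF >= 0.05 and missing <= 0.15 on the included lines.
#' @param karyotypes a [karyotype_table()] (needed for `factored_out`).
#' @param covariates a [line_covariates()]; Wolbachia enters as a 0/1 fixed
#'   effect (missing status treated as absent).
#' @param method `"full"`, `"ld"`, `"loco"` or `"factored_out"`.
#' @param grms precomputed [build_grms()] output (built on the fly if NULL —
#'   pass it when running several methods or traits).
#' @param n_perm number of trait permutations (default 100; 0 = observed
#'   run only).
#' @param seed master seed for the permutation streams.
#' @param factored_inversions inversions residualized out under
#'   `factored_out` (default: all in `karyotypes`).
#' @return a list of `gwa_run` objects (one per trait), each with `trait`,
#'   `method`, `results` (per-variant data.frame: id, arm, pos, maf, score,
#'   p, beta, se, skipped), `perm_p` (variants x n_perm matrix of permuted
#'   p-values) and `seed`.
#' @export
run_gwa <- function(traits, panel, karyotypes, covariates,
                    method = c("full", "ld", "loco", "factored_out"),
                    grms = NULL, n_perm = 100L, seed = 1L,
                    factored_inversions = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.numeric(traits) && !is.null(names(traits))) {
    tm <- trait_matrix(matrix(traits, ncol = 1,
                              dimnames = list(names(traits), "trait")))
  } else tm <- traits
  stopifnot(inherits(tm, "trait_matrix"))
  if (is.null(grms)) {
    grms <- switch(method,
                   full = , factored_out =
                     list(full = grm_vanraden(select_variants(panel, "full"))),
                   ld = list(ld = grm_gcta(select_variants(panel, "ld"),
                                           drop_monomorphic = TRUE)),
                   loco = build_grms(panel))
  }
  wolb <- as.numeric(covariates$wolbachia[match(panel$line_ids,
                                                covariates$line_id)] ==
                       "present")
  wolb[is.na(wolb)] <- 0
  names(wolb) <- panel$line_ids

  lapply(tm$traits, function(tr) {
    y0 <- tm$values[, tr]
    names(y0) <- tm$line_ids
    y0 <- y0[!is.na(y0)]
    if (method == "factored_out")
      y0 <- factored_out_residuals(y0, karyotypes, factored_inversions)
    run_gwa_one(tr, y0, panel, wolb, method, grms, n_perm, seed)
  })
}

# One trait x one method, observed + permutations.
run_gwa_one <- function(trait, y, panel, wolb, method, grms, n_perm, seed) {
  ids <- names(y)
  X <- matrix(wolb[ids], ncol = 1, dimnames = list(ids, "wolbachia"))
  grm_for <- function(arm) {
    switch(method,
           full = , factored_out = grms$full,
           ld = grms$ld,
           loco = grms$loco[[arm]] %||%
             stop("missing LOCO GRM for arm ", arm))
  }
  arms <- if (method == "loco") unique(panel$variants$arm) else "all"
  # cache one eigendecomposition per GRM, on the included line set
  eigs <- lapply(unique(arms), function(a) {
    K <- grm_for(if (a == "all") arms[1] else a)
    grm_eigen(K$K[ids, ids])
  })
  names(eigs) <- unique(arms)

  score_once <- function(yy) {
    parts <- lapply(arms, function(a) {
      vs <- if (a == "all") seq_len(nrow(panel$variants))
      else which(panel$variants$arm == a)
      fit <- fit_null_lmm(yy, K = NULL, covariates = X, eig = eigs[[a]])
      s <- score_test(fit, panel$dosage[ids, vs, drop = FALSE])
      s$arm <- panel$variants$arm[vs]
      s$pos <- panel$variants$pos[vs]
      s
    })
    out <- do.call(rbind, parts)
    out[match(panel$variants$id, out$id),
        c("id", "arm", "pos", "n_used", "maf", "missing_rate",
          "score", "p", "beta", "se", "skipped")]
  }
  results <- score_once(y)
  perm_p <- NULL
  if (n_perm > 0) {
    perm_p <- matrix(NA_real_, nrow(results), n_perm,
                     dimnames = list(results$id, NULL))
    for (r in seq_len(n_perm)) {
      yp <- with_seed(child_seed(seed, "perm", trait, method, r), {
        v <- sample(unname(y))
        names(v) <- ids
        v
      })
      perm_p[, r] <- score_once(yp)$p
    }
  }
  structure(list(trait = trait, method = method, results = results,
                 perm_p = perm_p, n_perm = n_perm, seed = seed,
                 trait_sd = stats::sd(y)),
            class = "gwa_run")
}

#' @export
print.gwa_run <- function(x, ...) {
  cat("gwa_run:", x$trait, "/", x$method, "-",
      sum(!is.na(x$results$p)), "variants scored,",
      x$n_perm, "permutations\n")
  invisible(x)
}

#' Write per-variant GWA results as TSV
#'
#' @param run a `gwa_run`.
#' @param path output path.
#' @export
write_gwa <- function(run, path) {
  utils::write.table(run$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
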