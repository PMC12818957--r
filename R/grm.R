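## Genomic relatedness matrices under three recipes (VanRaden full-genome,
## GCTA on an LD-pruned set, leave-one-chromosome-out) plus the greedy LD
## pruner.

#' Construct a relatedness-matrix object
#'
#' @param K symmetric numeric matrix with line ids as dimnames.
#' @param method one of `"vanraden_full"`, `"gcta_ld"`, `"gcta_loco"`.
#' @param excluded_arm arm excluded (LOCO) or `NA`.
#' @param variant_set_descriptor free-text description of the variant set
#'   (filters and count) that produced `K`.
#' @return object of class `relatedness_matrix`.
#' @export
relatedness_matrix <- function(K, method, excluded_arm = NA_character_,
                               variant_set_descriptor = "") {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
    stop("K must be symmetric")
  K <- (K + t(K)) / 2
  structure(list(K = K, line_ids = rownames(K), method = method,
                 excluded_arm = excluded_arm,
                 variant_set_descriptor = variant_set_descriptor),
            class = "relatedness_matrix")
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  cat("relatedness_matrix (", x$method, "): ", length(x$line_ids), " lines",
      if (!is.na(x$excluded_arm)) paste0("; excluding arm ", x$excluded_arm),
      "\n  variants: ", x$variant_set_descriptor, "\n", sep = "")
  invisible(x)
}

#' VanRaden genomic relatedness matrix
#'
#' `K = Z Z' / (2 * sum_j p_j (1 - p_j))` where `Z` is the dosage matrix
#' centered columnwise at `2 p_j` (`p_j` = alternate-allele frequency) and
#' missing dosages are mean-imputed (set to `2 p_j`) before centering.  The
#' full-genome recipe filters to MAF > 0.05 and missing rate < 0.20 before
#' calling this.
#'
#' @param panel a [genotype_panel()] (apply [filter_variants()] first for the
#'   standard recipe).
#' @return a [relatedness_matrix()] with method `"vanraden_full"`.
#' @export
grm_vanraden <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"),
            length(panel$line_ids) >= 2, nrow(panel$variants) >= 1)
  if (any(colSums(!is.na(panel$dosage)) == 0))
    stop("all-missing variant present; filter before constructing the GRM")
  dos <- panel$dosage
  p <- colSums(dos, na.rm = TRUE) / (2 * colSums(!is.na(dos)))
  Z <- sweep(dos, 2, 2 * p)
  Z[is.na(Z)] <- 0  # mean imputation: missing centered value is 0
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all variants monomorphic")
  K <- tcrossprod(Z) / denom
  relatedness_matrix(K, "vanraden_full",
                     variant_set_descriptor =
                       sprintf("%d variants, VanRaden full recipe",
                               ncol(dos)))
}

#' GCTA genomic relatedness matrix
#'
#' `K_ik = (1/M_ik) * sum_j z_ij z_kj` with per-variant standardized dosages
#' `z_ij = (g_ij - 2 p_j) / sqrt(2 p_j (1 - p_j))`; missing entries are
#' excluded pairwise, with `M_ik` the number of variants observed in both
#' lines.  The LD recipe filters to MAF > 0.05, missing rate < 0.15 and an
#' LD-pruned set (see [ld_prune()]) before calling this.
#'
#' @param panel a [genotype_panel()].
#' @param drop_monomorphic drop monomorphic variants with a message rather
#'   than erroring (used by [grm_loco()] after arm subsetting).
#' @return a [relatedness_matrix()] with method `"gcta_ld"`.
#' @export
grm_gcta <- function(panel, drop_monomorphic = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"),
            length(panel$line_ids) >= 2, nrow(panel$variants) >= 1)
  dos <- panel$dosage
  p <- colSums(dos, na.rm = TRUE) / (2 * colSums(!is.na(dos)))
  mono <- !is.finite(p) | p <= 0 | p >= 1
  if (any(mono)) {
    if (!drop_monomorphic)
      stop("monomorphic variant(s): ",
           paste(utils::head(colnames(dos)[mono], 5), collapse = ", "))
    message("dropping ", sum(mono), " monomorphic variant(s)")
    dos <- dos[, !mono, drop = FALSE]
    p <- p[!mono]
    if (ncol(dos) == 0) stop("no variants remain after dropping monomorphic")
  }
  Z <- sweep(sweep(dos, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  obs <- !is.na(Z)
  Z[!obs] <- 0
  M <- tcrossprod(obs * 1)  # pairwise count of co-observed variants
  if (any(M == 0)) stop("line pair with no co-observed variants")
  K <- tcrossprod(Z) / M
  relatedness_matrix(K, "gcta_ld",
                     variant_set_descriptor =
                       sprintf("%d variants, GCTA standardized, pairwise M",
                               ncol(dos)))
}

#' Leave-one-chromosome-out GRM
#'
#' Identical to [grm_gcta()] on the variant subset excluding one arm, so that
#' variants on the scored arm (and any inversion there) do not contribute to
#' the relatedness correction.
#'
#' @param panel a [genotype_panel()] (LD recipe already applied).
#' @param excluded_arm arm to leave out.
#' @return a [relatedness_matrix()] with method `"gcta_loco"`.
#' @export
grm_loco <- function(panel, excluded_arm) {
  stopifnot(inherits(panel, "genotype_panel"), length(excluded_arm) == 1)
  keep <- which(panel$variants$arm != excluded_arm)
  if (length(keep) == 0) stop("no variants remain after excluding arm ",
                              excluded_arm)
  out <- grm_gcta(panel_subset(panel, variants = keep),
                  drop_monomorphic = TRUE)
  out$method <- "gcta_loco"
  out$excluded_arm <- as.character(excluded_arm)
  out$variant_set_descriptor <- paste0(out$variant_set_descriptor,
                                       ", arm ", excluded_arm, " excluded")
  out
}

#' Greedy LD pruning
#'
#' Scans each arm left to right in position order; a variant is dropped when
#' its squared Pearson correlation of dosages (pairwise-complete) with any
#' already-retained variant within `window_bp` exceeds `r2_max`.  Earlier
#' positions win ties, so the result is deterministic.
#'
#' @param panel a [genotype_panel()].
#' @param r2_max maximum tolerated pairwise r-squared (default 0.2).
#' @param window_bp window width in bp; pairs at distance `<= window_bp` are
#'   compared (default 5000).
#' @return character vector of retained variant ids, in panel order.
#' @export
ld_prune <- function(panel, r2_max = 0.2, window_bp = 5000) {
  stopifnot(inherits(panel, "genotype_panel"))
  v <- panel$variants
  kept <- character(0)
  for (arm in unique(v$arm)) {
    idx <- which(v$arm == arm)
    idx <- idx[order(v$pos[idx])]
    kept_idx <- integer(0)
    kept_pos <- numeric(0)
    for (j in idx) {
      near <- kept_idx[v$pos[j] - kept_pos <= window_bp]
      drop <- FALSE
      for (i in near) {
        r <- suppressWarnings(
          stats::cor(panel$dosage[, i], panel$dosage[, j],
                     use = "pairwise.complete.obs"))
        if (is.finite(r) && r^2 > r2_max) { drop <- TRUE; break }
      }
      if (!drop) {
        kept_idx <- c(kept_idx, j)
        kept_pos <- c(kept_pos, v$pos[j])
      }
    }
    kept <- c(kept, v$id[kept_idx])
  }
  kept[order(match(kept, v$id))]
}

#' Apply a variant-selection recipe
#'
#' Convenience wrapper bundling the three standard recipes:
#' `full` = MAF > 0.05 & missing < 0.20;
#' `ld` = MAF > 0.05 & missing < 0.15, then [ld_prune()];
#' `loco` = the `ld` recipe restricted to arms other than `excluded_arm`
#' (the pruned set is computed once on all arms so the per-arm subsets
#' partition it).
#'
#' @param panel a [genotype_panel()].
#' @param recipe `"full"`, `"ld"` or `"loco"`.
#' @param excluded_arm required for `"loco"`.
#' @param r2_max,window_bp pruning parameters for the `ld`/`loco` recipes.
#' @return the selected [genotype_panel()].
#' @export
select_variants <- function(panel, recipe = c("full", "ld", "loco"),
                            excluded_arm = NULL, r2_max = 0.2,
                            window_bp = 5000) {
  recipe <- match.arg(recipe)
  if (recipe == "full") return(filter_variants(panel, 0.05, 0.20))
  p <- filter_variants(panel, 0.05, 0.15)
  keep <- ld_prune(p, r2_max = r2_max, window_bp = window_bp)
  p <- panel_subset(p, variants = match(keep, p$variants$id))
  if (recipe == "loco") {
    if (is.null(excluded_arm)) stop("loco recipe needs excluded_arm")
    keep2 <- which(p$variants$arm != excluded_arm)
    if (length(keep2) == 0) stop("no variants remain after excluding arm ",
                                 excluded_arm)
    p <- panel_subset(p, variants = keep2)
  }
  p
}

#' Serialize / read a relatedness matrix as TSV
#'
#' Square matrix with line ids as header row and first column.
#'
#' @param grm a [relatedness_matrix()].
#' @param path file path.
#' @export
write_grm <- function(grm, path) {
  tab <- data.frame(line_id = grm$line_ids, grm$K, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @param method,excluded_arm metadata restored on read.
#' @export
read_grm <- function(path, method = "vanraden_full",
                     excluded_arm = NA_character_) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  K <- as.matrix(tab[, -1, drop = FALSE])
  rownames(K) <- as.character(tab[[1]])
  relatedness_matrix(K, method, excluded_arm, "read from file")
}
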