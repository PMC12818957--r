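## Shared domain containers: genotype panels, karyotypes, traits, inversions,
## covariates; readers/writers for the plain-text formats the pipeline touches;
## variant/trait filtering; region classification relative to inversions.

VALID_KARYOTYPES <- c("INV", "STD", "HET")

#' Construct a genotype panel
#'
#' A genotype panel holds an alternate-allele dosage matrix (lines x variants,
#' entries in \{0, 1, 2, NA\}) together with per-variant metadata.  Minor
#' allele frequency and missing rate are (re)derived from the dosage matrix at
#' construction, so they are always consistent with it.  Panels of fully
#' inbred lines carry only dosages 0/2 (plus NA), but heterozygous dosage 1 is
#' permitted so that real panel files load.
#'
#' @param dosage numeric matrix, lines x variants; rownames are line ids and
#'   colnames variant ids (both required and unique).
#' @param variants data.frame with columns `id`, `arm`, `pos` (1-based),
#'   `ref`, `alt`, in the same order as the dosage columns.
#' @return an object of class `genotype_panel`: a list with elements
#'   `dosage`, `variants` (metadata plus derived `maf`, `missing_rate`) and
#'   `line_ids`.
#' @export
genotype_panel <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), is.data.frame(variants))
  req <- c("id", "arm", "pos", "ref", "alt")
  if (!all(req %in% names(variants)))
    stop("variants must have columns: ", paste(req, collapse = ", "))
  if (nrow(variants) != ncol(dosage))
    stop("variants rows (", nrow(variants), ") != dosage columns (",
         ncol(dosage), ")")
  if (is.null(rownames(dosage))) stop("dosage must have line ids as rownames")
  if (anyDuplicated(rownames(dosage))) stop("duplicate line ids")
  if (anyDuplicated(variants$id))
    stop("duplicate variant id: ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
  ok <- is.na(dosage) | dosage %in% c(0, 1, 2)
  if (!all(ok)) stop("dosage entries must be 0, 1, 2 or NA")
  if (any(variants$pos < 1)) stop("positions must be >= 1")
  colnames(dosage) <- variants$id
  variants <- variants[, req, drop = FALSE]
  variants$pos <- as.integer(variants$pos)
  d <- derive_variant_stats(dosage)
  variants$maf <- d$maf
  variants$missing_rate <- d$missing_rate
  rownames(variants) <- NULL
  structure(list(dosage = dosage, variants = variants,
                 line_ids = rownames(dosage)),
            class = "genotype_panel")
}

# maf (folded alt-allele frequency) and missing rate per dosage column,
# computed from non-missing entries only.
derive_variant_stats <- function(dosage) {
  n_obs <- colSums(!is.na(dosage))
  p <- ifelse(n_obs > 0, colSums(dosage, na.rm = TRUE) / (2 * n_obs), NA_real_)
  list(maf = pmin(p, 1 - p),
       alt_freq = p,
       missing_rate = colSums(is.na(dosage)) / nrow(dosage))
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$line_ids), "lines x",
      nrow(x$variants), "variants on arm(s)",
      paste(sort(unique(x$variants$arm)), collapse = ", "), "\n")
  invisible(x)
}

# Subset a panel, re-deriving maf/missing_rate (line subsets change both).
panel_subset <- function(panel, lines = NULL, variants = NULL) {
  d <- panel$dosage
  v <- panel$variants
  if (!is.null(variants)) {
    d <- d[, variants, drop = FALSE]
    v <- v[variants, , drop = FALSE]
  }
  if (!is.null(lines)) d <- d[lines, , drop = FALSE]
  genotype_panel(d, v[, c("id", "arm", "pos", "ref", "alt")])
}

#' Filter variants on minor allele frequency and missingness
#'
#' Retains variants with `maf > maf_min` and `missing_rate < missing_max`
#' (both strict, so boundary values are excluded); variant order is preserved.
#'
#' @param panel a [genotype_panel()].
#' @param maf_min minor-allele-frequency threshold in `[0, 0.5]`; default 0.05.
#' @param missing_max missing-rate threshold in `[0, 1]`; default 0.20.
#' @return the filtered `genotype_panel` (possibly with zero variants).
#' @export
filter_variants <- function(panel, maf_min = 0.05, missing_max = 0.20) {
  stopifnot(inherits(panel, "genotype_panel"),
            maf_min >= 0, maf_min <= 0.5, missing_max >= 0, missing_max <= 1)
  keep <- which(panel$variants$maf > maf_min &
                  panel$variants$missing_rate < missing_max)
  panel_subset(panel, variants = keep)
}

#' Construct a karyotype table
#'
#' @param call character matrix, lines x inversions, entries in
#'   `"INV"`, `"STD"`, `"HET"` or `NA`; rownames are line ids and colnames
#'   inversion names (unique).
#' @return an object of class `karyotype_table`.
#' @export
karyotype_table <- function(call) {
  stopifnot(is.matrix(call), is.character(call))
  if (is.null(rownames(call)) || is.null(colnames(call)))
    stop("call matrix needs line ids (rownames) and inversion names (colnames)")
  if (anyDuplicated(colnames(call))) stop("inversion names must be unique")
  bad <- !is.na(call) & !(call %in% VALID_KARYOTYPES)
  if (any(bad))
    stop("invalid karyotype call(s): ", paste(unique(call[bad]), collapse = ", "))
  structure(list(call = call, line_ids = rownames(call),
                 inversions = colnames(call)),
            class = "karyotype_table")
}

#' @export
print.karyotype_table <- function(x, ...) {
  cat("karyotype_table:", length(x$line_ids), "lines x",
      length(x$inversions), "inversion(s):",
      paste(x$inversions, collapse = ", "), "\n")
  invisible(x)
}

#' Define inversions by breakpoint coordinates
#'
#' @param name inversion names (unique).
#' @param arm chromosome arm of each inversion.
#' @param start,end 1-based inclusive breakpoint coordinates, `start < end`.
#' @param buffer_bp breakpoint-buffer width in basepairs (default 2 Mb), the
#'   distance from a breakpoint within which linkage to the inversion is
#'   considered strong.
#' @return data.frame of class `inversion_def`.
#' @export
inversion_def <- function(name, arm, start, end, buffer_bp = 2000000L) {
  stopifnot(length(name) == length(arm), length(arm) == length(start),
            length(start) == length(end))
  if (anyDuplicated(name)) stop("inversion names must be unique")
  if (any(start >= end)) stop("start must be < end")
  out <- data.frame(name = as.character(name), arm = as.character(arm),
                    start = as.integer(start), end = as.integer(end),
                    buffer_bp = as.integer(rep_len(buffer_bp, length(name))),
                    stringsAsFactors = FALSE)
  class(out) <- c("inversion_def", "data.frame")
  out
}

#' Construct a trait matrix
#'
#' @param values numeric matrix, lines x traits, with missing entries allowed;
#'   rownames line ids, colnames trait names.
#' @param category per-trait class label; one of `"Behavior"`,
#'   `"Life-History"`, `"Morphology"`, `"Physiology"`, `"Stress-resistance"`,
#'   `"other"`.  Defaults to `"other"`.
#' @return object of class `trait_matrix` with derived `n_lines` (non-missing
#'   count per trait).
#' @export
trait_matrix <- function(values, category = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values needs line ids (rownames) and trait names (colnames)")
  cats <- c("Behavior", "Life-History", "Morphology", "Physiology",
            "Stress-resistance", "other")
  if (is.null(category)) category <- rep("other", ncol(values))
  category <- rep_len(as.character(category), ncol(values))
  if (!all(category %in% cats))
    stop("trait category must be one of: ", paste(cats, collapse = ", "))
  structure(list(values = values, line_ids = rownames(values),
                 traits = colnames(values), category = category,
                 n_lines = colSums(!is.na(values))),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("trait_matrix:", length(x$line_ids), "lines x", length(x$traits),
      "traits; n_lines range", min(x$n_lines), "-", max(x$n_lines), "\n")
  invisible(x)
}

#' Drop traits measured on too few lines
#'
#' @param traits a [trait_matrix()].
#' @param min_lines minimum number of lines with a non-missing value; traits
#'   with `n_lines < min_lines` are removed (default 75).
#' @return the filtered `trait_matrix`.
#' @export
filter_traits <- function(traits, min_lines = 75L) {
  stopifnot(inherits(traits, "trait_matrix"), min_lines >= 1)
  keep <- traits$n_lines >= min_lines
  trait_matrix(traits$values[, keep, drop = FALSE], traits$category[keep])
}

#' Per-line covariates
#'
#' @param line_ids character vector of line ids.
#' @param wolbachia endosymbiont infection status, `"present"`, `"absent"` or
#'   `NA`, recycled to length.
#' @param ancestry_african optional admixture proportion in `[0, 1]`.
#' @return data.frame of class `line_covariates`.
#' @export
line_covariates <- function(line_ids, wolbachia = NA_character_,
                            ancestry_african = NA_real_) {
  wolbachia <- rep_len(as.character(wolbachia), length(line_ids))
  ancestry_african <- rep_len(as.numeric(ancestry_african), length(line_ids))
  bad <- !is.na(wolbachia) & !(wolbachia %in% c("present", "absent"))
  if (any(bad)) stop("wolbachia must be 'present', 'absent' or NA")
  if (any(!is.na(ancestry_african) &
            (ancestry_african < 0 | ancestry_african > 1)))
    stop("ancestry fractions must lie in [0, 1]")
  out <- data.frame(line_id = as.character(line_ids), wolbachia = wolbachia,
                    ancestry_african = ancestry_african,
                    stringsAsFactors = FALSE)
  class(out) <- c("line_covariates", "data.frame")
  out
}

#' Classify variant positions relative to inversions
#'
#' A position is `inside` if it falls within any inversion on its arm
#' (breakpoints inclusive), `breakpoint_buffer` if within `buffer_bp` of
#' either breakpoint of such an inversion but not inside it, and `outside`
#' otherwise.
#'
#' @param arm,pos vectors (recycled against one another) of arm labels and
#'   1-based positions.
#' @param inversions an [inversion_def()] table.
#' @param buffer_bp buffer width; defaults to the per-inversion `buffer_bp`.
#' @param known_arms optional character vector of valid arms; positions on an
#'   arm outside this set raise an error.
#' @return character vector in `c("inside", "breakpoint_buffer", "outside")`.
#' @export
classify_region <- function(arm, pos, inversions, buffer_bp = NULL,
                            known_arms = NULL) {
  stopifnot(inherits(inversions, "inversion_def"))
  n <- max(length(arm), length(pos))
  arm <- rep_len(as.character(arm), n)
  pos <- rep_len(as.numeric(pos), n)
  if (!is.null(known_arms) && !all(arm %in% known_arms))
    stop("unknown arm(s): ",
         paste(unique(arm[!(arm %in% known_arms)]), collapse = ", "))
  inside_any <- rep(FALSE, n)
  buffer_any <- rep(FALSE, n)
  for (k in seq_len(nrow(inversions))) {
    on_arm <- arm == inversions$arm[k]
    if (!any(on_arm)) next
    buf <- if (is.null(buffer_bp)) inversions$buffer_bp[k] else buffer_bp
    s <- inversions$start[k]; e <- inversions$end[k]
    inside <- on_arm & pos >= s & pos <= e
    near <- on_arm & !inside & (abs(pos - s) <= buf | abs(pos - e) <= buf)
    inside_any <- inside_any | inside
    buffer_any <- buffer_any | near
  }
  ifelse(inside_any, "inside",
         ifelse(buffer_any, "breakpoint_buffer", "outside"))
}

## ---------------------------------------------------------------------------
## Readers / writers

#' Read a genotype panel from VCF or TSV
#'
#' VCF input (v4.x, GT field, biallelic records only) is parsed with
#' \pkg{vcfR}; multi-allelic records are rejected with a report of their
#' positions.  TSV input is a tab-separated dosage matrix with a header row,
#' line ids in the first column, and variant ids of the form
#' `arm_pos_ref_alt` as the remaining column names.
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return a [genotype_panel()].
#' @export
read_genotypes <- function(path, dialect = c("auto", "vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (dialect == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix[, c("CHROM", "POS", "ID", "REF", "ALT"), drop = FALSE]
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    stop("multi-allelic record(s) rejected at: ",
         paste(paste0(fix$CHROM[multi], ":", fix$POS[multi]), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = "_")[is.na(ids) | ids == "."]
  dos <- apply(gt, 2, gt_to_dosage)
  dos <- matrix(dos, nrow = nrow(gt),
                dimnames = list(NULL, colnames(gt)))
  dosage <- t(dos)
  colnames(dosage) <- ids
  variants <- data.frame(id = ids, arm = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_panel(dosage, variants)
}

# "0/0" -> 0, "0/1" -> 1, "1|1" -> 2, "./." or NA -> NA
gt_to_dosage <- function(gt) {
  alleles <- strsplit(gsub("\\|", "/", gt), "/", fixed = TRUE)
  vapply(alleles, function(a) {
    if (length(a) == 0 || any(is.na(a)) || any(a == ".")) return(NA_real_)
    a <- suppressWarnings(as.numeric(a))
    if (any(is.na(a)) || any(a > 1)) return(NA_real_)
    sum(a)
  }, numeric(1))
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  line_ids <- as.character(tab[[1]])
  dosage <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(dosage) <- "double"
  rownames(dosage) <- line_ids
  ids <- colnames(dosage)
  parts <- strsplit(ids, "_", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 4
  if (any(bad))
    stop("variant id(s) not of form arm_pos_ref_alt: ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  variants <- data.frame(
    id = ids,
    arm = vapply(parts, `[`, character(1), 1),
    pos = as.integer(vapply(parts, `[`, character(1), 2)),
    ref = vapply(parts, `[`, character(1), 3),
    alt = vapply(parts, `[`, character(1), 4),
    stringsAsFactors = FALSE)
  genotype_panel(dosage, variants)
}

#' Write a genotype panel to VCF or TSV
#'
#' The VCF writer emits a minimal plain-text VCF v4.2 with GT-only genotypes
#' (dosage 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`, NA -> `./.`);
#' `read_genotypes()` round-trips it exactly.
#'
#' @param panel a [genotype_panel()].
#' @param path output path.
#' @param dialect `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(panel, "genotype_panel"))
  if (dialect == "tsv") {
    tab <- data.frame(line_id = panel$line_ids, panel$dosage,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  v <- panel$variants
  # variants must be sorted within arm for downstream scanning tools
  ord <- order(v$arm, v$pos)
  v <- v[ord, , drop = FALSE]
  dos <- panel$dosage[, ord, drop = FALSE]
  gt <- matrix("./.", nrow = nrow(v), ncol = length(panel$line_ids))
  gt[t(dos) == 0] <- "0/0"
  gt[t(dos) == 1] <- "0/1"
  gt[t(dos) == 2] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$line_ids), collapse = "\t"))
  body <- paste(v$arm, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read/write karyotype tables, trait matrices, covariates and inversions
#'
#' Plain TSV, header row, line ids (or inversion names) in the first column.
#'
#' @param path file path.
#' @name io_tsv
NULL

#' @rdname io_tsv
#' @param karyotypes a [karyotype_table()].
#' @export
write_karyotypes <- function(karyotypes, path) {
  tab <- data.frame(line_id = karyotypes$line_ids, karyotypes$call,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname io_tsv
#' @export
read_karyotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  karyotype_table(m)
}

#' @rdname io_tsv
#' @param traits a [trait_matrix()].
#' @export
write_traits <- function(traits, path) {
  tab <- data.frame(line_id = traits$line_ids, traits$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname io_tsv
#' @param category optional per-trait categories applied on read.
#' @export
read_traits <- function(path, category = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  trait_matrix(m, category)
}

#' @rdname io_tsv
#' @param inversions an [inversion_def()] table.
#' @export
write_inversions <- function(inversions, path) {
  utils::write.table(inversions[, c("name", "arm", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io_tsv
#' @param buffer_bp breakpoint buffer applied to all inversions on read.
#' @export
read_inversions <- function(path, buffer_bp = 2000000L) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  inversion_def(tab$name, tab$arm, tab$start, tab$end, buffer_bp)
}
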