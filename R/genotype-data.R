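#' Construct a genotype matrix object
#'
#' The central in-memory container of the pipeline: an additive-dosage matrix
#' oriented SNPs x subjects, with per-SNP metadata and missingness stored as
#' `NA` entries (never a sentinel dosage).
#'
#' @param dosages integer matrix of alternate-allele counts in \{0,1,2\}, SNPs in
#'   rows, subjects in columns; `NA` marks a missing genotype.
#' @param snp_meta data.frame with one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `ref`, `alt`, and optionally `panel_label` (`"CHD"`/`"T2D"`),
#'   `risk_direction` (`"risk"`/`"protective"`), `gwas_p`, `gwas_or`.
#' @param subject_ids character vector of subject identifiers, one per column.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snp_meta, subject_ids) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (nrow(snp_meta) != nrow(dosages))
    stop("snp_meta has ", nrow(snp_meta), " rows but dosage matrix has ",
         nrow(dosages), " SNPs")
  if (length(subject_ids) != ncol(dosages))
    stop("subject_ids length ", length(subject_ids),
         " does not match ", ncol(dosages), " columns")
  subject_ids <- as.character(subject_ids)
  snp_ids <- as.character(snp_meta$snp_id)
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids: ",
                                   paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids: ",
                                       paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must lie in {0,1,2} or be NA")
  rownames(dosages) <- snp_ids
  colnames(dosages) <- subject_ids
  rownames(snp_meta) <- NULL
  structure(list(dosages = dosages, snp_meta = snp_meta,
                 subject_ids = subject_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "SNPs x", ncol(x$dosages), "subjects;",
      sum(is.na(x$dosages)), "missing entries\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by SNPs and/or subjects
#'
#' @param g a `genotype_matrix`.
#' @param snps,subjects index, logical, or id vectors; `NULL` keeps all.
#' @return A `genotype_matrix` restricted to the selection, metadata aligned.
#' @export
subset_genotypes <- function(g, snps = NULL, subjects = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  ridx <- if (is.null(snps)) seq_len(nrow(g$dosages)) else {
    if (is.character(snps)) match(snps, rownames(g$dosages)) else which_index(snps, nrow(g$dosages))
  }
  if (anyNA(ridx)) stop("unknown SNP id(s): ",
                        paste(snps[is.na(ridx)], collapse = ", "))
  cidx <- if (is.null(subjects)) seq_len(ncol(g$dosages)) else {
    if (is.character(subjects)) match(subjects, g$subject_ids) else which_index(subjects, ncol(g$dosages))
  }
  if (anyNA(cidx)) stop("unknown subject id(s): ",
                        paste(subjects[is.na(cidx)], collapse = ", "))
  genotype_matrix(g$dosages[ridx, cidx, drop = FALSE],
                  g$snp_meta[ridx, , drop = FALSE],
                  g$subject_ids[cidx])
}

which_index <- function(i, n) {
  if (is.logical(i)) which(i) else as.integer(i)
}

#' Derive the disease-pattern label from two binary statuses
#'
#' Deterministic map: (1,1) -> comorbid, (1,0) -> chd_only, (0,1) -> t2d_only,
#' (0,0) -> none.
#'
#' @param chd,t2d binary vectors of equal length.
#' @return factor with levels comorbid, chd_only, t2d_only, none.
#' @export
disease_pattern <- function(chd, t2d) {
  stopifnot(length(chd) == length(t2d))
  lab <- ifelse(chd == 1 & t2d == 1, "comorbid",
         ifelse(chd == 1 & t2d == 0, "chd_only",
         ifelse(chd == 0 & t2d == 1, "t2d_only", "none")))
  factor(lab, levels = c("comorbid", "chd_only", "t2d_only", "none"))
}

#' Construct a phenotype table
#'
#' One row per subject with both disease statuses, the derived pattern label,
#' and covariates (age, sex, BMI, optional ancestry PCs).
#'
#' @param df data.frame with at least `subject_id`, `chd`, `t2d`, `age`,
#'   `sex`, `bmi`; optional `PC1..PCn` columns and extra traits.
#' @return A `phenotype_table` (a data.frame subclass) with a recomputed
#'   `pattern` column.
#' @export
phenotype_table <- function(df) {
  req <- c("subject_id", "chd", "t2d", "age", "sex", "bmi")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("phenotype table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) stop("duplicate subject ids in phenotype table")
  # subjects lacking either diagnosis cannot be assigned a pattern: drop, log
  bad <- is.na(df$chd) | is.na(df$t2d)
  if (any(bad)) {
    message("dropping ", sum(bad), " subject(s) with missing disease status")
    df <- df[!bad, , drop = FALSE]
  }
  stopifnot(all(df$chd %in% 0:1), all(df$t2d %in% 0:1))
  recomputed <- disease_pattern(df$chd, df$t2d)
  if (!is.null(df$pattern) && !all(as.character(df$pattern) == as.character(recomputed)))
    stop("provided pattern column disagrees with (chd, t2d) statuses")
  df$pattern <- recomputed
  rownames(df) <- NULL
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Align a genotype matrix and phenotype table on subject id
#'
#' Explicit join on `subject_id`; subjects present in only one input are
#' dropped with a message. Never joins positionally.
#'
#' @param g a `genotype_matrix`.
#' @param pheno a `phenotype_table`.
#' @return list with elements `genotypes` and `phenotypes` in identical
#'   subject order.
#' @export
align_subjects <- function(g, pheno) {
  common <- intersect(g$subject_ids, pheno$subject_id)
  if (!length(common)) stop("no subjects shared between genotypes and phenotypes")
  n_drop <- (length(g$subject_ids) - length(common)) +
    (nrow(pheno) - length(common))
  if (n_drop > 0) message("align_subjects: dropping ", n_drop,
                          " unmatched subject record(s)")
  list(genotypes = subset_genotypes(g, subjects = common),
       phenotypes = pheno[match(common, pheno$subject_id), , drop = FALSE])
}

#' Construct a SNP set (fuzzy bicluster)
#'
#' @param k rank of the factorization the set came from.
#' @param factor_index index i of the factor, 1 <= i <= k.
#' @param snp_ids,subject_ids member identifier vectors (non-empty).
#' @return object of class `snp_set` with label `G_<k>_<i>`.
#' @export
snp_set <- function(k, factor_index, snp_ids, subject_ids) {
  stopifnot(k >= 2, factor_index >= 1, factor_index <= k,
            length(snp_ids) > 0, length(subject_ids) > 0)
  structure(list(label = sprintf("G_%d_%d", k, factor_index),
                 k = as.integer(k), factor_index = as.integer(factor_index),
                 snp_ids = as.character(snp_ids),
                 subject_ids = as.character(subject_ids)),
            class = "snp_set")
}

#' @export
print.snp_set <- function(x, ...) {
  cat(x$label, ": ", length(x$snp_ids), " SNPs x ",
      length(x$subject_ids), " subjects\n", sep = "")
  invisible(x)
}
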