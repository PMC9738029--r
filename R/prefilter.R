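#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test of HWE genotype proportions given the allele counts:
#' enumerates the full conditional distribution of heterozygote counts and
#' sums the probabilities of all outcomes no more probable than the observed
#' one (standard exact P, no mid-p).
#'
#' @param n_aa,n_ab,n_bb genotype counts (B the minor allele by convention;
#'   the test is symmetric in the allele labels).
#' @return exact two-sided P value in (0, 1].
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_b <- 2 * n_bb + n_ab                 # rare-allele count (either allele works)
  if (n_b > n) n_b <- 2 * n - n_b
  hets <- seq.int(n_b %% 2, n_b, by = 2) # feasible heterozygote counts
  # log conditional probability up to a constant, then normalize
  lp <- vapply(hets, function(h) {
    hom_b <- (n_b - h) / 2
    hom_a <- n - h - hom_b
    h * log(2) - lfactorial(hom_a) - lfactorial(h) - lfactorial(hom_b)
  }, numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- match(n_ab, hets)
  if (is.na(obs)) stop("inconsistent genotype counts for HWE test")
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

#' Apply genotype quality-control filters
#'
#' Filters applied in a fixed order: (1) SNPs with missing rate >=
#' `snp_missing_max` removed; (2) SNPs with MAF <= `maf_min` removed;
#' (3) SNPs with exact HWE P < `hwe_p_min` removed; (4) subjects with
#' missing rate >= `subject_missing_max` removed. Thresholds are closed
#' exactly as written (>= and <= remove).
#'
#' @param g a [genotype_matrix()].
#' @param snp_missing_max,maf_min,hwe_p_min,subject_missing_max thresholds.
#' @return the filtered [genotype_matrix()] with attribute `"qc_report"`, a
#'   data.frame of per-step removal counts.
#' @export
qc_filter <- function(g, snp_missing_max = 0.05, maf_min = 0.01,
                      hwe_p_min = 1e-6, subject_missing_max = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"), nrow(g$dosages) > 0)
  report <- data.frame(step = character(), snps_removed = integer(),
                       subjects_removed = integer(), stringsAsFactors = FALSE)
  add <- function(step, s, subj) rbind(report, data.frame(
    step = step, snps_removed = s, subjects_removed = subj,
    stringsAsFactors = FALSE))

  miss_rate <- rowMeans(is.na(g$dosages))
  keep <- miss_rate < snp_missing_max
  report <- add("snp_missingness", sum(!keep), 0L)
  g <- subset_genotypes(g, snps = keep)
  if (!nrow(g$dosages)) stop("QC removed all SNPs (missingness step)")

  af <- rowMeans(g$dosages, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- maf > maf_min
  report <- add("maf", sum(!keep), 0L)
  g <- subset_genotypes(g, snps = keep)
  if (!nrow(g$dosages)) stop("QC removed all SNPs (MAF step)")

  hwe <- apply(g$dosages, 1, function(d) {
    d <- d[!is.na(d)]
    hwe_exact_p(sum(d == 0), sum(d == 1), sum(d == 2))
  })
  keep <- hwe >= hwe_p_min
  report <- add("hwe", sum(!keep), 0L)
  g <- subset_genotypes(g, snps = keep)
  if (!nrow(g$dosages)) stop("QC removed all SNPs (HWE step)")

  subj_miss <- colMeans(is.na(g$dosages))
  keep <- subj_miss < subject_missing_max
  report <- add("subject_call_rate", 0L, sum(!keep))
  g <- subset_genotypes(g, subjects = keep)

  attr(g, "qc_report") <- report
  g
}

#' Per-SNP logistic regression prescreen
#'
#' One additive-coded logistic fit per SNP (iteratively reweighted least
#' squares via `glm`), adjusting for the supplied covariates. Subjects with a
#' missing dosage at a SNP are dropped for that SNP only. Wald P values from
#' beta/se. Non-convergent or separated fits are flagged with `p = 1`.
#'
#' @param g a [genotype_matrix()].
#' @param y binary disease status aligned to subjects (both classes present).
#' @param covariates optional numeric matrix/data.frame, one row per subject.
#' @param disease label recorded in the result (`"CHD"` or `"T2D"`).
#' @return data.frame with `snp_id`, `disease`, `beta`, `se`, `or_value`,
#'   `wald_p`, `flagged`.
#' @export
logistic_gwas <- function(g, y, covariates = NULL, disease = "CHD") {
  stopifnot(inherits(g, "genotype_matrix"), all(y %in% 0:1))
  if (length(unique(y)) < 2) stop("y must contain both classes")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == ncol(g$dosages))
    if (qr(cbind(1, covariates))$rank < ncol(covariates) + 1)
      stop("covariate matrix is rank deficient")
  }
  res <- lapply(seq_len(nrow(g$dosages)), function(i) {
    d <- g$dosages[i, ]
    ok <- !is.na(d)
    row <- data.frame(snp_id = rownames(g$dosages)[i], disease = disease,
                      beta = NA_real_, se = NA_real_, or_value = NA_real_,
                      wald_p = 1, flagged = TRUE, stringsAsFactors = FALSE)
    if (length(unique(d[ok])) < 2 || length(unique(y[ok])) < 2) return(row)
    X <- if (is.null(covariates)) data.frame(dosage = d[ok])
         else data.frame(dosage = d[ok], covariates[ok, , drop = FALSE])
    fit <- suppressWarnings(stats::glm(y[ok] ~ ., data = X, family = stats::binomial()))
    cf <- summary(fit)$coefficients
    if (!fit$converged || !"dosage" %in% rownames(cf) ||
        abs(cf["dosage", "Estimate"]) > 15) return(row)   # separation guard
    row$beta <- cf["dosage", "Estimate"]
    row$se <- cf["dosage", "Std. Error"]
    row$or_value <- exp(row$beta)
    row$wald_p <- cf["dosage", "Pr(>|z|)"]
    row$flagged <- FALSE
    row
  })
  do.call(rbind, res)
}

#' Pool the two disease panels into the factorization input matrix
#'
#' SNPs with a prescreen Wald P below `p_thresh` for either disease are
#' retained; each is labeled with its panel disease and effect direction
#' (OR > 1 means risk). A SNP passing for both diseases is assigned to the
#' disease with the smaller P and flagged as dual.
#'
#' @param g the QC'd [genotype_matrix()] both prescreens were run on.
#' @param chd_results,t2d_results outputs of [logistic_gwas()].
#' @param p_thresh loose-association threshold (default 5e-5).
#' @return a [genotype_matrix()] restricted to the pooled panel, with
#'   `panel_label`, `risk_direction`, `gwas_p`, `gwas_or` and `dual_hit`
#'   filled in `snp_meta`.
#' @export
pool_panels <- function(g, chd_results, t2d_results, p_thresh = 5e-5) {
  stopifnot(inherits(g, "genotype_matrix"))
  merge_one <- function(res) res[match(rownames(g$dosages), res$snp_id), ]
  chd <- merge_one(chd_results); t2d <- merge_one(t2d_results)
  hit_chd <- !is.na(chd$wald_p) & !chd$flagged & chd$wald_p < p_thresh
  hit_t2d <- !is.na(t2d$wald_p) & !t2d$flagged & t2d$wald_p < p_thresh
  keep <- hit_chd | hit_t2d
  if (!any(keep)) stop("no SNP passed the prescreen threshold ", p_thresh,
                       " for either disease: empty pooled panel")
  dual <- hit_chd & hit_t2d
  use_chd <- hit_chd & (!dual | chd$wald_p <= t2d$wald_p)
  out <- subset_genotypes(g, snps = keep)
  sel <- which(keep)
  out$snp_meta$panel_label <- ifelse(use_chd[sel], "CHD", "T2D")
  best <- ifelse(use_chd[sel], chd$or_value[sel], t2d$or_value[sel])
  out$snp_meta$risk_direction <- ifelse(best > 1, "risk", "protective")
  out$snp_meta$gwas_p <- ifelse(use_chd[sel], chd$wald_p[sel], t2d$wald_p[sel])
  out$snp_meta$gwas_or <- best
  out$snp_meta$dual_hit <- dual[sel]
  out
}

#' Ancestry principal components from the genotype matrix
#'
#' PCs of the mean-imputed, per-SNP standardized dosage matrix, computed over
#' subjects. Deterministic sign convention: within each component the loading
#' of largest magnitude is positive.
#'
#' @param g a [genotype_matrix()].
#' @param n_pcs number of components (0 returns an empty block).
#' @return numeric matrix, subjects x `n_pcs`, columns `PC1..`.
#' @export
compute_pcs <- function(g, n_pcs = 10) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- ncol(g$dosages)
  if (n_pcs == 0)
    return(matrix(numeric(0), nrow = n, ncol = 0,
                  dimnames = list(g$subject_ids, NULL)))
  if (n < n_pcs || nrow(g$dosages) < n_pcs)
    stop("need at least ", n_pcs, " subjects and SNPs for ", n_pcs, " PCs")
  Z <- g$dosages
  mu <- rowMeans(Z, na.rm = TRUE)
  for (i in seq_len(nrow(Z))) Z[i, is.na(Z[i, ])] <- mu[i]
  s <- apply(Z, 1, stats::sd)
  if (all(s == 0)) stop("degenerate genotype matrix: all SNPs constant")
  Z <- (Z - mu)[s > 0, , drop = FALSE] / s[s > 0]
  pc <- stats::prcomp(t(Z), center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                       # fixed sign convention
    ld <- pc$rotation[, j]
    if (ld[which.max(abs(ld))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- g$subject_ids
  scores
}
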