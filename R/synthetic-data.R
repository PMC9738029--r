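#' Describe a planted SNP x subject bicluster
#'
#' A planted set forces a block of the genotype matrix to a single concordant
#' dosage and optionally shifts the disease liability of its member subjects,
#' emulating a subgroup of subjects sharing the same homozygous allele pattern
#' at a subset of SNPs.
#'
#' @param snp_indices,subject_indices 1-based row/column indices of the block.
#' @param concordant_genotype dosage written into every planted cell (0, 1 or 2).
#' @param penetrance_shift log-odds added to member subjects' liability for the
#'   target disease(s).
#' @param target_disease `"CHD"`, `"T2D"` or `"both"`.
#' @return object of class `planted_set`.
#' @export
planted_set <- function(snp_indices, subject_indices, concordant_genotype = 2,
                        penetrance_shift = 0, target_disease = c("both", "CHD", "T2D")) {
  target_disease <- match.arg(target_disease)
  stopifnot(length(snp_indices) > 0, length(subject_indices) > 0,
            concordant_genotype %in% 0:2)
  structure(list(snp_indices = as.integer(snp_indices),
                 subject_indices = as.integer(subject_indices),
                 concordant_genotype = as.integer(concordant_genotype),
                 penetrance_shift = penetrance_shift,
                 target_disease = target_disease),
            class = "planted_set")
}

#' Configure a synthetic case-control cohort
#'
#' Defaults encode the discovery-cohort geometry the pipeline targets: 441
#' subjects split 61/91/97/192 across the four disease patterns (comorbid,
#' CHD-only, T2D-only, none) and a pooled panel of 110 CHD- plus 83
#' T2D-associated variants (193 SNPs).
#'
#' @param n_subjects total cohort size.
#' @param n_snps_chd,n_snps_t2d panel sizes for the two diseases.
#' @param pattern_counts named or ordered counts (comorbid, chd_only,
#'   t2d_only, none); must sum to `n_subjects`.
#' @param planted_sets list of [planted_set()] objects.
#' @param maf_range background minor-allele-frequency range, within (0.01, 0.5).
#' @param missing_rate missing-completely-at-random genotype rate, in \[0, 0.05\].
#' @param covariate_effects named log-odds per covariate unit (age, sex, bmi)
#'   applied to both disease liabilities.
#' @param seed integer RNG seed.
#' @return validated `cohort_config` object.
#' @export
cohort_config <- function(n_subjects = 441, n_snps_chd = 110, n_snps_t2d = 83,
                          pattern_counts = c(comorbid = 61, chd_only = 91,
                                             t2d_only = 97, none = 192),
                          planted_sets = list(),
                          maf_range = c(0.05, 0.45), missing_rate = 0.01,
                          covariate_effects = c(age = 0.02, sex = 0.3, bmi = 0.04),
                          seed = 1L) {
  pattern_counts <- as.integer(pattern_counts)
  names(pattern_counts) <- c("comorbid", "chd_only", "t2d_only", "none")
  if (sum(pattern_counts) != n_subjects)
    stop("pattern_counts sum to ", sum(pattern_counts),
         " but n_subjects is ", n_subjects)
  if (length(maf_range) != 2 || maf_range[1] <= 0.01 || maf_range[2] >= 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an increasing pair inside (0.01, 0.5)")
  if (missing_rate < 0 || missing_rate > 0.05)
    stop("missing_rate must lie in [0, 0.05]")
  n_snps <- n_snps_chd + n_snps_t2d
  for (ps in planted_sets) {
    stopifnot(inherits(ps, "planted_set"))
    if (max(ps$snp_indices) > n_snps)
      stop("planted set references SNP index beyond the panel (",
           max(ps$snp_indices), " > ", n_snps, ")")
    if (max(ps$subject_indices) > n_subjects)
      stop("planted set references subject index beyond the cohort")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_snps_chd = as.integer(n_snps_chd),
                 n_snps_t2d = as.integer(n_snps_t2d),
                 pattern_counts = pattern_counts,
                 planted_sets = planted_sets,
                 maf_range = maf_range, missing_rate = missing_rate,
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  # inverse-CDF truncation: exact, vectorized, no rejection loop
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a cohort with planted biclusters and two correlated diseases
#'
#' Background genotypes are per-SNP binomial(2, MAF) draws; planted blocks are
#' overwritten with their concordant dosage; disease statuses come from
#' independent logistic liabilities per disease combining covariate effects
#' and planted penetrance shifts; the four disease-pattern counts are then
#' made exact by stratified reassignment of the subjects whose liabilities
#' least support their drawn pattern (guaranteed to terminate). Finally,
#' genotypes are masked missing-completely-at-random at the configured rate.
#'
#' @param config a [cohort_config()].
#' @return list with `genotypes` (a [genotype_matrix()]), `phenotypes`
#'   (a [phenotype_table()]) and `ground_truth` (the planted sets, with member
#'   ids resolved to SNP/subject identifiers).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  m <- config$n_snps_chd + config$n_snps_t2d
  snp_ids <- sprintf("snp%03d", seq_len(m))
  subject_ids <- sprintf("S%04d", seq_len(n))

  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  dos <- matrix(stats::rbinom(m * n, 2L, rep(maf, times = n)), nrow = m)
  for (ps in config$planted_sets)
    dos[ps$snp_indices, ps$subject_indices] <- ps$concordant_genotype

  age <- rtruncnorm1(n, 60, 8, 40, 85)
  sex <- stats::rbinom(n, 1L, 0.5)
  bmi <- stats::rnorm(n, 25, 3)
  ce <- config$covariate_effects
  # center covariates so the intercept controls prevalence directly
  cov_lp <- ce[["age"]] * (age - 60) + ce[["sex"]] * (sex - 0.5) +
    ce[["bmi"]] * (bmi - 25)

  shift <- matrix(0, n, 2, dimnames = list(NULL, c("CHD", "T2D")))
  for (ps in config$planted_sets) {
    tg <- if (ps$target_disease == "both") c("CHD", "T2D") else ps$target_disease
    shift[ps$subject_indices, tg] <- shift[ps$subject_indices, tg] + ps$penetrance_shift
  }

  pc <- config$pattern_counts
  prev_chd <- (pc["comorbid"] + pc["chd_only"]) / n
  prev_t2d <- (pc["comorbid"] + pc["t2d_only"]) / n
  eta_chd <- stats::qlogis(prev_chd) + cov_lp + shift[, "CHD"]
  eta_t2d <- stats::qlogis(prev_t2d) + cov_lp + shift[, "T2D"]
  p_chd <- stats::plogis(eta_chd)
  p_t2d <- stats::plogis(eta_t2d)
  chd <- stats::rbinom(n, 1L, p_chd)
  t2d <- stats::rbinom(n, 1L, p_t2d)

  res <- enforce_pattern_counts(chd, t2d, p_chd, p_t2d, pc)
  chd <- res$chd; t2d <- res$t2d

  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(m * n) < config$missing_rate, m, n)
    dos[mask] <- NA_integer_
  }

  panel <- rep(c("CHD", "T2D"), c(config$n_snps_chd, config$n_snps_t2d))
  snp_meta <- data.frame(snp_id = snp_ids, chrom = "1",
                         pos = seq_len(m) * 1000L,
                         ref = "A", alt = "G",
                         panel_label = panel,
                         risk_direction = NA_character_,
                         gwas_p = NA_real_, gwas_or = NA_real_,
                         stringsAsFactors = FALSE)
  g <- genotype_matrix(dos, snp_meta, subject_ids)
  pheno <- phenotype_table(data.frame(subject_id = subject_ids,
                                      chd = chd, t2d = t2d,
                                      age = age, sex = sex, bmi = bmi,
                                      stringsAsFactors = FALSE))
  truth <- lapply(config$planted_sets, function(ps) {
    ps$snp_ids <- snp_ids[ps$snp_indices]
    ps$subject_ids <- subject_ids[ps$subject_indices]
    ps
  })
  list(genotypes = g, phenotypes = pheno, ground_truth = truth)
}

# Stratified reassignment to exact pattern counts: while some pattern has a
# surplus, move the surplus subject with the highest liability-model
# probability of a deficit pattern into that pattern. Each move reduces total
# absolute imbalance by 2, so the loop terminates in at most n steps.
enforce_pattern_counts <- function(chd, t2d, p_chd, p_t2d, target) {
  pat_prob <- cbind(comorbid = p_chd * p_t2d,
                    chd_only = p_chd * (1 - p_t2d),
                    t2d_only = (1 - p_chd) * p_t2d,
                    none     = (1 - p_chd) * (1 - p_t2d))
  status_of <- list(comorbid = c(1L, 1L), chd_only = c(1L, 0L),
                    t2d_only = c(0L, 1L), none = c(0L, 0L))
  pat <- as.character(disease_pattern(chd, t2d))
  repeat {
    counts <- vapply(names(target), function(p) sum(pat == p), integer(1))
    diff <- counts - target
    if (all(diff == 0L)) break
    deficit <- names(target)[which.max(-diff)]
    surplus <- names(target)[which.max(diff)]
    cand <- which(pat == surplus)
    pick <- cand[which.max(pat_prob[cand, deficit])]
    pat[pick] <- deficit
  }
  chd <- vapply(pat, function(p) status_of[[p]][1], integer(1), USE.NAMES = FALSE)
  t2d <- vapply(pat, function(p) status_of[[p]][2], integer(1), USE.NAMES = FALSE)
  list(chd = chd, t2d = t2d)
}

#' Score recovery of planted sets by found SNP sets
#'
#' For each planted (truth) set, the best Jaccard similarity over all found
#' sets, computed separately on SNP ids and subject ids. Order-invariant.
#'
#' @param found list of [snp_set()] objects (may be empty: scores are 0).
#' @param truth non-empty list of resolved planted sets (elements carry
#'   `snp_ids` and `subject_ids`).
#' @return data.frame with one row per truth set: `snp_jaccard`,
#'   `subject_jaccard`, and the label of the best subject-matching found set.
#' @export
score_recovery <- function(found, truth) {
  if (!length(truth)) stop("truth must be non-empty")
  out <- lapply(truth, function(tr) {
    if (!length(found))
      return(data.frame(snp_jaccard = 0, subject_jaccard = 0,
                        best_label = NA_character_, stringsAsFactors = FALSE))
    sj <- vapply(found, function(f) jaccard(f$snp_ids, tr$snp_ids), numeric(1))
    uj <- vapply(found, function(f) jaccard(f$subject_ids, tr$subject_ids), numeric(1))
    data.frame(snp_jaccard = max(sj), subject_jaccard = max(uj),
               best_label = found[[which.max(sj + uj)]]$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
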