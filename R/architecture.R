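#' Partition the cohort into the four disease-pattern phenotype sets
#'
#' @param pheno a [phenotype_table()].
#' @return named list of subject-id vectors: `comorbid`, `chd_only`,
#'   `t2d_only`, `none` (a partition; comorbid with chd_only covers all CHD
#'   cases, comorbid with t2d_only all T2D cases).
#' @export
define_phenotype_sets <- function(pheno) {
  split(pheno$subject_id, pheno$pattern)
}

#' Jaccard similarity of two id sets
#'
#' `|A n B| / |A u B|`; 0 when both sets are empty.
#'
#' @param a_ids,b_ids id vectors (duplicates ignored).
#' @return similarity in \[0, 1\].
#' @export
jaccard <- function(a_ids, b_ids) {
  u <- length(union(a_ids, b_ids))
  if (u == 0) return(0)
  length(intersect(a_ids, b_ids)) / u
}

#' Upper-tail hypergeometric overlap test
#'
#' `P(X >= observed overlap)` for the intersection of two subsets drawn from
#' a finite universe, computed by exact summation of the hypergeometric mass
#' in log space.
#'
#' @param a_ids,b_ids id vectors, subsets of the universe.
#' @param universe_n universe size (>= both set sizes).
#' @return list with `overlap` and `p`.
#' @export
hypergeom_overlap <- function(a_ids, b_ids, universe_n) {
  a_ids <- unique(a_ids); b_ids <- unique(b_ids)
  na <- length(a_ids); nb <- length(b_ids)
  stopifnot(universe_n >= na, universe_n >= nb)
  ov <- length(intersect(a_ids, b_ids))
  if (ov == 0) return(list(overlap = 0L, p = 1))
  hi <- min(na, nb)
  lp <- stats::dhyper(ov:hi, na, universe_n - na, nb, log = TRUE)
  mx <- max(lp)
  list(overlap = ov, p = min(1, exp(mx + log(sum(exp(lp - mx))))))
}

#' Relate SNP sets to the disease-pattern phenotype sets
#'
#' All set-by-pattern hypergeometric tests on shared subjects, universe = the
#' analyzed cohort.
#'
#' @param sets list of [snp_set()] objects.
#' @param pheno_sets output of [define_phenotype_sets()].
#' @param universe_n cohort size.
#' @return data.frame of edges: `label`, `pattern`, `overlap`, `set_size`,
#'   `pattern_size`, `p`, `jaccard`.
#' @export
relate_to_patterns <- function(sets, pheno_sets, universe_n) {
  rows <- list()
  for (s in sets) for (pat in names(pheno_sets)) {
    hg <- hypergeom_overlap(s$subject_ids, pheno_sets[[pat]], universe_n)
    rows[[length(rows) + 1L]] <- data.frame(
      label = s$label, pattern = pat, overlap = hg$overlap,
      set_size = length(s$subject_ids),
      pattern_size = length(pheno_sets[[pat]]),
      p = hg$p, jaccard = jaccard(s$subject_ids, pheno_sets[[pat]]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Remove redundant SNP sets by greedy Jaccard filtering
#'
#' Sets are ranked by the strength of their best phenotype relation (smallest
#' hypergeometric p over the four patterns; ties broken by smaller rank `k`,
#' then smaller factor index — deterministic and input-order independent) and
#' accepted greedily: a set is kept only if both its SNP-Jaccard and its
#' subject-Jaccard against every already-kept set stay at or below
#' `jc_thresh` ("over 0.8" read as strictly greater than).
#'
#' @param sets list of [snp_set()] objects.
#' @param relations output of [relate_to_patterns()] covering `sets`.
#' @param jc_thresh redundancy threshold (default 0.8).
#' @return the retained subset of `sets`, in acceptance order, with the
#'   ranking p attached as attribute `"best_p"`.
#' @export
redundancy_filter <- function(sets, relations, jc_thresh = 0.8) {
  if (!length(sets)) return(sets)
  best_p <- vapply(sets, function(s) {
    min(relations$p[relations$label == s$label])
  }, numeric(1))
  ks <- vapply(sets, `[[`, integer(1), "k")
  fi <- vapply(sets, `[[`, integer(1), "factor_index")
  ord <- order(best_p, ks, fi)
  kept <- list(); kept_p <- numeric()
  for (i in ord) {
    cand <- sets[[i]]
    redundant <- any(vapply(kept, function(kp)
      jaccard(cand$snp_ids, kp$snp_ids) > jc_thresh ||
      jaccard(cand$subject_ids, kp$subject_ids) > jc_thresh, logical(1)))
    if (!redundant) {
      kept[[length(kept) + 1L]] <- cand
      kept_p <- c(kept_p, best_p[i])
    }
  }
  attr(kept, "best_p") <- kept_p
  kept
}

#' Significant genotype-phenotype relations among retained sets
#'
#' Hypergeometric tests of every retained set against every disease pattern;
#' an edge is significant when its p falls below `alpha / n_retained_sets`
#' (the four patterns are not separately corrected, so 23 retained sets at
#' alpha 0.05 give the threshold 2.17e-3).
#'
#' @param sets retained (redundancy-filtered) list of [snp_set()] objects.
#' @param pheno_sets output of [define_phenotype_sets()].
#' @param universe_n cohort size.
#' @param alpha family-wise level (default 0.05).
#' @param panel optional `snp_meta` for annotating each set's effect-direction
#'   profile.
#' @return data.frame of significant edges (possibly empty) with attribute
#'   `"threshold"`; columns as in [relate_to_patterns()] plus `significant`
#'   and, with `panel`, `direction_profile`.
#' @export
build_architecture <- function(sets, pheno_sets, universe_n, alpha = 0.05,
                               panel = NULL) {
  rel <- relate_to_patterns(sets, pheno_sets, universe_n)
  if (is.null(rel)) rel <- data.frame(label = character(), pattern = character(),
                                      overlap = integer(), p = numeric(),
                                      jaccard = numeric(), stringsAsFactors = FALSE)
  thr <- if (length(sets)) bonferroni_threshold(alpha, length(sets)) else alpha
  rel$significant <- rel$p < thr
  if (!is.null(panel) && nrow(rel)) {
    prof <- vapply(sets, function(s) {
      ors <- panel$gwas_or[match(s$snp_ids, panel$snp_id)]
      ors <- ors[!is.na(ors)]
      if (!length(ors)) "unknown"
      else if (all(ors > 1)) "risk"
      else if (all(ors < 1)) "protective" else "mixed"
    }, character(1))
    names(prof) <- vapply(sets, `[[`, character(1), "label")
    rel$direction_profile <- prof[rel$label]
  }
  out <- rel[rel$significant, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  attr(out, "all_relations") <- rel
  out
}
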