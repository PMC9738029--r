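#' Posterior descriptors for one SNP set
#'
#' Three families of indicators per set: disease risk (percentage of CHD and
#' of T2D cases among member subjects), SNP composition (percentage of member
#' SNPs from each disease panel) and effect direction (percentage of member
#' SNPs with prescreen OR > 1, within each panel). Raw fractions are kept;
#' rounding to integer percent happens only in report writers.
#'
#' @param s a [snp_set()].
#' @param pheno a [phenotype_table()] covering the set's subjects.
#' @param panel `snp_meta` data.frame with `snp_id`, `panel_label`, `gwas_or`.
#' @return one-row data.frame of descriptors.
#' @export
describe_set <- function(s, pheno, panel) {
  stopifnot(inherits(s, "snp_set"))
  pi <- match(s$subject_ids, pheno$subject_id)
  if (anyNA(pi)) stop("unresolvable subject id(s) in ", s$label, ": ",
                      paste(s$subject_ids[is.na(pi)], collapse = ", "))
  si <- match(s$snp_ids, panel$snp_id)
  if (anyNA(si)) stop("unresolvable SNP id(s) in ", s$label, ": ",
                      paste(s$snp_ids[is.na(si)], collapse = ", "))
  sub <- pheno[pi, ]
  snps <- panel[si, ]
  is_chd <- snps$panel_label == "CHD"
  pct <- function(x) if (length(x)) 100 * mean(x) else NA_real_
  data.frame(label = s$label,
             n_snps = length(s$snp_ids),
             n_subjects = length(s$subject_ids),
             chd_risk_pct = pct(sub$chd == 1),
             t2d_risk_pct = pct(sub$t2d == 1),
             composition_chd_pct = pct(is_chd),
             composition_t2d_pct = pct(!is_chd),
             risk_or_gt1_chd_pct = pct(snps$gwas_or[is_chd] > 1),
             risk_or_gt1_t2d_pct = pct(snps$gwas_or[!is_chd] > 1),
             stringsAsFactors = FALSE)
}

#' Descriptor table for a list of SNP sets
#'
#' @inheritParams describe_set
#' @param sets list of [snp_set()] objects.
#' @return data.frame, one row per set (Table-style report; use
#'   [write_descriptor_tsv()] for the rounded file form).
#' @export
describe_sets <- function(sets, pheno, panel) {
  do.call(rbind, lapply(sets, describe_set, pheno = pheno, panel = panel))
}

#' Cohort-level purity of SNP sets
#'
#' A set "mixes" panels when both CHD- and T2D-panel SNPs occur among its
#' members, and mixes effect directions when both OR > 1 and OR < 1 SNPs do.
#'
#' @param sets non-empty list of [snp_set()] objects.
#' @param panel `snp_meta` data.frame.
#' @return list with `panel_mix_fraction` and `direction_mix_fraction`.
#' @export
purity_summary <- function(sets, panel) {
  stopifnot(length(sets) > 0)
  mix <- vapply(sets, function(s) {
    idx <- match(s$snp_ids, panel$snp_id)
    labs <- panel$panel_label[idx]
    dirs <- panel$gwas_or[idx] > 1
    c(length(unique(labs)) > 1, length(unique(dirs[!is.na(dirs)])) > 1)
  }, logical(2))
  list(panel_mix_fraction = mean(mix[1, ]),
       direction_mix_fraction = mean(mix[2, ]))
}

#' Write the descriptor table, rounded to integer percent
#' @param desc output of [describe_sets()].
#' @param path TSV path.
#' @export
write_descriptor_tsv <- function(desc, path) {
  num <- vapply(desc, is.numeric, logical(1)) & grepl("pct$", names(desc))
  desc[num] <- lapply(desc[num], function(x) round(x))
  utils::write.table(desc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
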