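#' Regenerate SNP sets in a replication cohort on the discovery panel
#'
#' Restricts the replication genotype matrix to the discovery panel's SNPs
#' and reruns the identical rank sweep (same k range, theta, tau, extraction
#' mode) with an independent seed.
#'
#' @param g_replication a [genotype_matrix()] for the held-out subjects.
#' @param panel_snp_ids SNP ids of the discovery panel.
#' @param k_min,k_max,theta,tau,mode,max_iter,tol sweep parameters — must
#'   mirror the discovery run.
#' @param seed independent replication seed.
#' @param coding passed to [encode_matrix()].
#' @return list of [snp_set()] objects from the replication sample.
#' @export
replicate_sweep <- function(g_replication, panel_snp_ids, k_min = 2,
                            k_max = NULL, theta = 0.5, tau = 0.6,
                            mode = "factor_wise", max_iter = 2000, tol = 1e-6,
                            seed = 2L, coding = "offset_dosage") {
  present <- intersect(panel_snp_ids, rownames(g_replication$dosages))
  if (!length(present)) stop("replication matrix shares no SNPs with the panel")
  if (length(present) < length(panel_snp_ids))
    message("replication matrix missing ",
            length(panel_snp_ids) - length(present), " panel SNP(s)")
  g <- subset_genotypes(g_replication, snps = present)
  X <- encode_matrix(g, coding)
  if (is.null(k_max)) k_max <- floor(sqrt(nrow(X)))
  run_sweep(X, k_min = k_min, k_max = k_max, theta = theta, tau = tau,
            mode = mode, max_iter = max_iter, tol = tol, seed = seed)
}

#' Match discovery SNP sets to replication SNP sets
#'
#' For each discovery set, the replication set minimizing the upper-tail
#' hypergeometric p on shared SNPs over the common panel; a discovery set is
#' flagged replicated when its best p falls below `p_match`. An underflowed
#' p of exactly 0 indicates total overlap.
#'
#' @param discovery_sets,replication_sets non-empty lists of [snp_set()].
#' @param panel_size size of the shared SNP universe.
#' @param p_match replication threshold (default 1e-3).
#' @return data.frame with one row per discovery set: `discovery_label`,
#'   `best_label`, `shared_snps`, `p`, `snp_jaccard`, `replicated`; the
#'   replicated fraction is attached as attribute `"replicated_fraction"`.
#' @export
match_snp_sets <- function(discovery_sets, replication_sets, panel_size,
                           p_match = 1e-3) {
  stopifnot(length(discovery_sets) > 0, length(replication_sets) > 0)
  rows <- lapply(discovery_sets, function(d) {
    ps <- vapply(replication_sets, function(r)
      hypergeom_overlap(d$snp_ids, r$snp_ids, panel_size)$p, numeric(1))
    best <- which.min(ps)
    r <- replication_sets[[best]]
    data.frame(discovery_label = d$label, best_label = r$label,
               shared_snps = length(intersect(d$snp_ids, r$snp_ids)),
               p = ps[best], snp_jaccard = jaccard(d$snp_ids, r$snp_ids),
               replicated = ps[best] < p_match, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "replicated_fraction") <- mean(out$replicated)
  out
}
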