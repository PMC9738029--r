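# Shared fixture builders: everything is generated in code at test time.

tiny_genotypes <- function(m = 10, n = 40, maf = 0.3, seed = 1) {
  set.seed(seed)
  dos <- matrix(rbinom(m * n, 2, maf), m, n)
  genotype_matrix(dos,
                  data.frame(snp_id = sprintf("s%02d", 1:m), chrom = "1",
                             pos = 1:m, ref = "A", alt = "G",
                             stringsAsFactors = FALSE),
                  sprintf("P%03d", 1:n))
}

tiny_pheno <- function(n = 40, prev_chd = 0.4, prev_t2d = 0.35, seed = 1) {
  set.seed(seed)
  phenotype_table(data.frame(subject_id = sprintf("P%03d", 1:n),
                             chd = rbinom(n, 1, prev_chd),
                             t2d = rbinom(n, 1, prev_t2d),
                             age = rnorm(n, 60, 8), sex = rbinom(n, 1, 0.5),
                             bmi = rnorm(n, 25, 3), stringsAsFactors = FALSE))
}

# a cohort with planted biclusters strong enough for recovery work
planted_cohort <- function(seed, n_sets = 2, shift = 1.5, missing_rate = 0) {
  blocks <- list(list(snps = 1:12, subj = 1:25, target = "both"),
                 list(snps = 30:45, subj = 101:130, target = "CHD"),
                 list(snps = 60:72, subj = 200:225, target = "T2D"),
                 list(snps = 120:135, subj = 300:330, target = "T2D"))
  ps <- lapply(blocks[seq_len(n_sets)], function(b)
    planted_set(b$snps, b$subj, 2, shift, b$target))
  simulate_cohort(cohort_config(planted_sets = ps, maf_range = c(0.05, 0.2),
                                missing_rate = missing_rate, seed = seed))
}

# independent exhaustive oracle for the upper-tail hypergeometric overlap
hypergeom_enum_oracle <- function(universe_n, a, b, k_obs) {
  subsets <- utils::combn(universe_n, b)
  mean(colSums(subsets <= a) >= k_obs)  # A = {1..a}
}

gini_coefficient <- function(x) {
  x <- sort(x)
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}
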