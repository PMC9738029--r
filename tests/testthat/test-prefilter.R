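test_that("HWE exact test matches a brute-force enumeration oracle", {
  # independent oracle: enumerate every feasible heterozygote count directly
  # from the factorial form of the conditional distribution
  oracle <- function(n_aa, n_ab, n_bb) {
    n <- n_aa + n_ab + n_bb
    nb <- 2 * n_bb + n_ab
    if (nb > n) nb <- 2 * n - nb
    hets <- seq(nb %% 2, nb, by = 2)
    pr <- sapply(hets, function(h) {
      bb <- (nb - h) / 2; aa <- n - h - bb
      exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) + lfactorial(nb) + lfactorial(2 * n - nb) - lfactorial(2 * n))
    })
    pr <- pr / sum(pr)  # normalize away any common constant
    sum(pr[pr <= pr[match(n_ab, hets)] * (1 + 1e-12)])
  }
  # n = 100, nA = nB = 100: perfectly HWE-proportioned counts are retained
  expect_equal(hwe_exact_p(25, 50, 25), oracle(25, 50, 25), tolerance = 1e-12)
  expect_gt(hwe_exact_p(25, 50, 25), 0.9)
  set.seed(1)
  for (i in 1:25) {
    n <- sample(10:120, 1)
    d <- rbinom(n, 2, runif(1, 0.1, 0.5))
    cnt <- c(sum(d == 0), sum(d == 1), sum(d == 2))
    expect_equal(hwe_exact_p(cnt[1], cnt[2], cnt[3]),
                 oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
  }
  # gross heterozygote deficit is detected
  expect_lt(hwe_exact_p(50, 0, 50), 1e-6)
})

test_that("qc_filter applies thresholds in order with closed boundaries", {
  g <- tiny_genotypes(m = 8, n = 50, maf = 0.3, seed = 4)
  g$dosages[1, 1:3] <- NA_integer_   # missing rate 6% >= 5% -> removed
  g$dosages[2, 1:2] <- NA_integer_   # 4% < 5% -> kept
  g$dosages[3, ] <- 0L               # monomorphic, MAF 0 <= 1% -> removed
  g$dosages[4, ] <- rep(c(0L, 2L), 25)  # het deficit -> HWE removed
  out <- qc_filter(g)
  kept <- rownames(out$dosages)
  expect_false(any(c("s01", "s03", "s04") %in% kept))
  expect_true("s02" %in% kept)
  rep <- attr(out, "qc_report")
  expect_equal(rep$step, c("snp_missingness", "maf", "hwe", "subject_call_rate"))
  expect_equal(rep$snps_removed, c(1L, 1L, 1L, 0L))
  # permuting subjects never changes which SNPs survive
  perm <- sample(ncol(g$dosages))
  g_perm <- subset_genotypes(g, subjects = perm)
  expect_setequal(rownames(qc_filter(g_perm)$dosages), kept)
})

test_that("logistic prescreen matches the 2x2 closed form and flags degeneracy", {
  # saturated check: dosage 0/1 only, no covariates -> beta is the log
  # cross-product odds ratio of the contingency table
  set.seed(8)
  n <- 400
  d <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + 0.9 * d))
  tab <- table(d, y)
  or_hand <- (tab["1", "1"] * tab["0", "0"]) / (tab["1", "0"] * tab["0", "1"])
  g <- genotype_matrix(matrix(as.integer(d), 1),
                       data.frame(snp_id = "s1", chrom = "1", pos = 1,
                                  ref = "A", alt = "G"),
                       as.character(1:n))
  res <- logistic_gwas(g, y)
  expect_equal(res$beta, log(or_hand), tolerance = 1e-6)
  expect_equal(res$or_value, exp(res$beta))
  # constant dosage -> flagged non-estimable with p = 1
  g0 <- genotype_matrix(matrix(1L, 1, n), g$snp_meta, as.character(1:n))
  res0 <- logistic_gwas(g0, y)
  expect_true(res0$flagged)
  expect_equal(res0$wald_p, 1)
})

test_that("null SNPs give uniform Wald p-values", {
  set.seed(12)
  n <- 500
  y <- rbinom(n, 1, 0.4)
  dos <- sapply(runif(200, 0.1, 0.4), function(m) rbinom(n, 2, m))
  g <- genotype_matrix(t(dos),
                       data.frame(snp_id = sprintf("s%03d", 1:200), chrom = "1",
                                  pos = 1:200, ref = "A", alt = "G"),
                       as.character(1:n))
  res <- logistic_gwas(g, y)
  ks <- suppressWarnings(ks.test(res$wald_p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pool_panels keeps prescreen hits with correct labels and dual rule", {
  g <- tiny_genotypes(m = 200, n = 60, seed = 9)
  mk <- function(p, disease) data.frame(snp_id = rownames(g$dosages),
                                        disease = disease, beta = 0.1, se = 0.1,
                                        or_value = 1.5, wald_p = p,
                                        flagged = FALSE, stringsAsFactors = FALSE)
  p_chd <- rep(1, 200); p_chd[1:110] <- 1e-6
  p_t2d <- rep(1, 200); p_t2d[111:193] <- 1e-6
  pooled <- pool_panels(g, mk(p_chd, "CHD"), mk(p_t2d, "T2D"))
  expect_equal(nrow(pooled$dosages), 193)
  expect_equal(sum(pooled$snp_meta$panel_label == "CHD"), 110)
  expect_equal(sum(pooled$snp_meta$panel_label == "T2D"), 83)
  expect_false(any(pooled$snp_meta$dual_hit))
  # dual hit assigned to the smaller p, flagged
  p_t2d2 <- p_t2d; p_t2d2[1] <- 1e-5   # SNP 1: CHD p 1e-6 < T2D p 1e-5
  pooled2 <- pool_panels(g, mk(p_chd, "CHD"), mk(p_t2d2, "T2D"))
  expect_equal(pooled2$snp_meta$panel_label[1], "CHD")
  expect_true(pooled2$snp_meta$dual_hit[1])
  # count identity |CHD| + |T2D| - |dual|
  expect_equal(nrow(pooled2$dosages), 110 + 84 - 1)
  # risk direction follows the OR
  expect_true(all(pooled$snp_meta$risk_direction == "risk"))
  # empty panel errors
  expect_error(pool_panels(g, mk(rep(1, 200), "CHD"), mk(rep(1, 200), "T2D")),
               "empty pooled panel")
})

test_that("principal components separate simulated subpopulations", {
  set.seed(15)
  m <- 150; n <- 100
  pop <- rep(0:1, each = n / 2)
  f1 <- runif(m, 0.1, 0.4); f2 <- pmin(f1 + 0.2, 0.9)  # Fst-like offset
  dos <- sapply(seq_len(n), function(j)
    rbinom(m, 2, if (pop[j] == 0) f1 else f2))
  g <- genotype_matrix(dos, data.frame(snp_id = sprintf("s%02d", 1:m),
                                       chrom = "1", pos = 1:m, ref = "A",
                                       alt = "G"), sprintf("P%03d", 1:n))
  pcs <- compute_pcs(g, 10)
  expect_gt(abs(cor(pcs[, 1], pop)), 0.9)
  # n_pcs = 0 yields an empty covariate block
  expect_equal(ncol(compute_pcs(g, 0)), 0)
  # duplicated subject columns receive identical coordinates
  g2 <- genotype_matrix(cbind(g$dosages[, 1], g$dosages[, 1:10]),
                        g$snp_meta, c("dup", sprintf("P%03d", 1:10)))
  pcs2 <- compute_pcs(g2, 3)
  expect_equal(unname(pcs2[1, ]), unname(pcs2[2, ]))
  # deterministic sign convention: recomputation is identical
  expect_identical(compute_pcs(g, 5), compute_pcs(g, 5))
})
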