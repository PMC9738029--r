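test_that("phenotype sets partition the cohort and satisfy the case identities", {
  # encode the reference subgroup sizes directly in statuses
  n <- 441
  chd <- c(rep(1, 61), rep(1, 91), rep(0, 97), rep(0, 192))
  t2d <- c(rep(1, 61), rep(0, 91), rep(1, 97), rep(0, 192))
  ph <- phenotype_table(data.frame(subject_id = sprintf("S%03d", 1:n),
                                   chd = chd, t2d = t2d, age = 60, sex = 1,
                                   bmi = 25))
  sets <- define_phenotype_sets(ph)
  expect_equal(lengths(sets)[c("comorbid", "chd_only", "t2d_only", "none")],
               c(comorbid = 61L, chd_only = 91L, t2d_only = 97L, none = 192L))
  expect_equal(length(sets$comorbid) + length(sets$chd_only), 152)
  expect_equal(length(sets$comorbid) + length(sets$t2d_only), 158)
  expect_equal(sum(lengths(sets)), n)
  expect_setequal(unlist(sets), ph$subject_id)
  # identities hold on generated cohorts too
  sim <- simulate_cohort(cohort_config(seed = 41))
  ps <- define_phenotype_sets(sim$phenotypes)
  expect_equal(length(ps$comorbid) + length(ps$chd_only),
               sum(sim$phenotypes$chd))
  expect_equal(length(ps$comorbid) + length(ps$t2d_only),
               sum(sim$phenotypes$t2d))
  # degenerate cohort: no cases at all
  ph0 <- phenotype_table(data.frame(subject_id = c("a", "b"), chd = 0, t2d = 0,
                                    age = 60, sex = 1, bmi = 25))
  expect_equal(lengths(define_phenotype_sets(ph0))[["none"]], 2L)
})

test_that("hypergeometric overlap matches direct enumeration and edge cases", {
  # N=10, |A|=5, |B|=4, overlap 3: count C(10,4) draws intersecting A in >= 3
  r <- hypergeom_overlap(1:5, c(3, 4, 5, 9), 10)
  expect_equal(r$overlap, 3L)
  expect_equal(r$p, hypergeom_enum_oracle(10, 5, 4, 3))
  expect_equal(r$p, 55 / 210)
  # disjoint sets: P(X >= 0) = 1
  expect_equal(hypergeom_overlap(1:3, 4:6, 10)$p, 1)
  # A = universe forces overlap = |B| with p = 1
  r2 <- hypergeom_overlap(1:10, c(2, 5), 10)
  expect_equal(r2$overlap, 2L)
  expect_equal(r2$p, 1)
})

test_that("jaccard matches hand enumeration", {
  expect_equal(jaccard(1:6, 1:6), 1)
  expect_equal(jaccard(1:3, 4:6), 0)
  expect_equal(jaccard(1:6, 4:9), 3 / 9)
  expect_equal(jaccard(character(), character()), 0)
})

test_that("redundancy_filter follows the greedy rule deterministically", {
  mkrel <- function(labels, ps) data.frame(label = labels, pattern = "comorbid",
                                           p = ps, stringsAsFactors = FALSE)
  # two identical sets: only the stronger (smaller p) kept
  a <- snp_set(2, 1, sprintf("s%d", 1:10), sprintf("P%d", 1:10))
  b <- snp_set(2, 2, sprintf("s%d", 1:10), sprintf("P%d", 1:10))
  kept <- redundancy_filter(list(a, b), mkrel(c("G_2_1", "G_2_2"), c(0.001, 0.01)))
  expect_equal(vapply(kept, `[[`, character(1), "label"), "G_2_1")
  # pairwise JC 0.5 on both dimensions: all kept
  c1 <- snp_set(2, 1, sprintf("s%d", 1:8), sprintf("P%d", 1:8))
  c2 <- snp_set(2, 2, sprintf("s%d", 3:10), sprintf("P%d", 3:10))
  expect_length(redundancy_filter(list(c1, c2),
                                  mkrel(c("G_2_1", "G_2_2"), c(0.01, 0.02))), 2)
  # A,B,C with JC(A,B) and JC(A,C) > 0.8, JC(B,C) small, p-order A < B < C:
  # greedy keeps only A
  A <- snp_set(3, 1, sprintf("s%d", 1:10), sprintf("P%d", 1:10))
  B <- snp_set(3, 2, sprintf("s%d", 1:9), sprintf("P%d", 1:9))   # JC 0.9 with A
  C <- snp_set(3, 3, sprintf("s%d", c(1:10, 11)), sprintf("P%d", c(1:10, 11)))
  rel <- mkrel(c("G_3_1", "G_3_2", "G_3_3"), c(0.001, 0.002, 0.003))
  kept2 <- redundancy_filter(list(A, B, C), rel)
  expect_equal(vapply(kept2, `[[`, character(1), "label"), "G_3_1")
  # boundary JC exactly 0.8 is kept ("over 0.8" is strict)
  D <- snp_set(4, 1, sprintf("s%d", 1:4), sprintf("P%d", 1:4))
  E <- snp_set(4, 2, sprintf("s%d", 1:5), sprintf("P%d", 1:5))  # JC = 4/5 = 0.8
  expect_length(redundancy_filter(list(D, E),
                                  mkrel(c("G_4_1", "G_4_2"), c(0.01, 0.02))), 2)
  # input order does not matter
  kept3 <- redundancy_filter(list(C, A, B), rel)
  expect_equal(vapply(kept3, `[[`, character(1), "label"), "G_3_1")
})

test_that("build_architecture finds a planted comorbidity relation", {
  sim <- simulate_cohort(cohort_config(seed = 43))
  pheno_sets <- define_phenotype_sets(sim$phenotypes)
  # a set whose subjects are exactly the comorbid subgroup
  s <- snp_set(2, 1, rownames(sim$genotypes$dosages)[1:5], pheno_sets$comorbid)
  rel <- relate_to_patterns(list(s), pheno_sets, nrow(sim$phenotypes))
  arch <- build_architecture(list(s), pheno_sets, nrow(sim$phenotypes))
  expect_true(any(arch$pattern == "comorbid"))
  expect_lt(arch$p[arch$pattern == "comorbid"], attr(arch, "threshold"))
  # 23 retained sets reproduce the reference threshold
  sets23 <- lapply(1:23, function(i) snp_set(23, i, "s1", "P1"))
  ph <- tiny_pheno(n = 30, seed = 1)
  arch23 <- build_architecture(sets23, define_phenotype_sets(ph), 30)
  expect_equal(signif(attr(arch23, "threshold"), 3), 2.17e-3)
  # zero retained sets: empty output
  arch0 <- build_architecture(list(), pheno_sets, nrow(sim$phenotypes))
  expect_equal(nrow(arch0), 0)
})
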