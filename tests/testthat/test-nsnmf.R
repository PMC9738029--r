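test_that("theta = 0 reduces to KL-NMF and reconstructs exact low-rank input", {
  set.seed(21)
  W0 <- matrix(runif(20 * 2), 20)
  H0 <- matrix(runif(2 * 30), 2)
  X <- W0 %*% H0
  fit <- nsnmf_factorize(X, k = 2, theta = 0, max_iter = 5000, tol = 1e-12,
                         seed = 1)
  expect_lt(tail(fit$objective_trace, 1), 1e-6 * sum(X))
})

test_that("objective trace is monotone non-increasing on any input", {
  set.seed(22)
  for (s in 1:4) {
    X <- matrix(sample(1:3, 25 * 40, TRUE), 25, 40)
    for (objective in c("kl", "frobenius")) {
      fit <- nsnmf_factorize(X, k = 3, theta = 0.5, max_iter = 300,
                             seed = s, objective = objective)
      expect_true(all(diff(fit$objective_trace) <= 1e-9),
                  info = paste("seed", s, objective))
    }
  }
})

test_that("higher theta produces sparser W on matched seeds", {
  set.seed(23)
  X <- matrix(runif(30 * 50, 0, 3), 30, 50)
  f0 <- nsnmf_factorize(X, k = 3, theta = 0, seed = 5)
  f9 <- nsnmf_factorize(X, k = 3, theta = 0.9, seed = 5)
  g0 <- mean(apply(f0$W, 2, gini_coefficient))
  g9 <- mean(apply(f9$W, 2, gini_coefficient))
  expect_gt(g9, g0)
})

test_that("reconstruction divergence does not increase with rank", {
  set.seed(24)
  X <- matrix(sample(1:3, 30 * 60, TRUE), 30, 60)
  for (s in 1:3) {
    d <- sapply(2:5, function(k)
      tail(nsnmf_factorize(X, k, theta = 0.5, max_iter = 600,
                           seed = s)$objective_trace, 1))
    expect_true(all(diff(d) <= 1e-6 * d[1]), info = paste("seed", s))
  }
})

test_that("encode_matrix offsets, reorients and mode-imputes", {
  g <- tiny_genotypes(m = 3, n = 3, seed = 1)
  g$dosages <- matrix(c(0L, 1L, 2L,  0L, 1L, 2L,  0L, NA, 2L), 3, 3,
                      byrow = TRUE, dimnames = dimnames(g$dosages))
  g$snp_meta$risk_direction <- c("risk", "protective", "risk")
  g$snp_meta$gwas_or <- c(1.5, 0.6, 1.5)
  X <- encode_matrix(g, "offset_dosage")
  expect_equal(unname(X[1, ]), c(1, 2, 3))
  # mode of (0, 2) ties to the smaller dosage -> impute 0 -> encode 1
  expect_equal(unname(X[3, ]), c(1, 1, 3))
  Xr <- encode_matrix(g, "risk_dosage")
  expect_equal(unname(Xr[2, ]), c(3, 2, 1))  # protective SNP flipped
  expect_equal(unname(Xr[1, ]), c(1, 2, 3))  # risk SNP unchanged
  expect_error(encode_matrix(g, "unknown_coding"))
})

test_that("extract_snp_sets applies the relative threshold exactly", {
  W <- cbind(c(1.0, 0.61, 0.59, 0.0), c(0.1, 0.1, 0.1, 0.8))
  H <- rbind(c(1, 0.5, 0.7), c(0.2, 1, 0.59))
  rownames(W) <- paste0("s", 1:4); colnames(H) <- paste0("P", 1:3)
  fit <- structure(list(W = W, H = H, theta = 0.5, k = 2L,
                        objective_trace = 1, seed = 1, converged = TRUE,
                        n_iter = 1L), class = "nsnmf_fit")
  sets <- extract_snp_sets(fit, tau = 0.6, mode = "factor_wise")
  expect_equal(sets[[1]]$snp_ids, c("s1", "s2"))
  expect_equal(sets[[1]]$subject_ids, c("P1", "P3"))
  expect_equal(sets[[1]]$label, "G_2_1")
  # tau = 1 keeps only the entities attaining the maximum
  sets1 <- extract_snp_sets(fit, tau = 1)
  expect_equal(sets1[[1]]$snp_ids, "s1")
  expect_equal(sets1[[2]]$snp_ids, "s4")
  # entity-wise mode thresholds against each entity's own max across factors
  setse <- extract_snp_sets(fit, tau = 0.6, mode = "entity_wise")
  expect_false("s4" %in% setse[[1]]$snp_ids)
  expect_true("s4" %in% setse[[2]]$snp_ids)
})

test_that("extraction is invariant to simultaneous row permutation", {
  set.seed(26)
  X <- matrix(sample(1:3, 20 * 30, TRUE), 20, 30,
              dimnames = list(sprintf("s%02d", 1:20), sprintf("P%02d", 1:30)))
  fit <- nsnmf_factorize(X, 3, theta = 0.5, seed = 2)
  perm <- sample(20)
  fit_p <- fit
  fit_p$W <- fit$W[perm, ]
  a <- extract_snp_sets(fit)
  b <- extract_snp_sets(fit_p)
  for (i in seq_along(a)) {
    expect_setequal(a[[i]]$snp_ids, b[[i]]$snp_ids)
    expect_identical(a[[i]]$subject_ids, b[[i]]$subject_ids)
  }
})

test_that("run_sweep set accounting and determinism", {
  set.seed(27)
  X <- matrix(sample(1:3, 20 * 40, TRUE), 20, 40,
              dimnames = list(sprintf("s%02d", 1:20), sprintf("P%02d", 1:40)))
  s2 <- run_sweep(X, 2, 2, max_iter = 100, seed = 1)
  expect_equal(vapply(s2, `[[`, character(1), "label"), c("G_2_1", "G_2_2"))
  s5 <- run_sweep(X, 2, 5, max_iter = 100, seed = 1)
  expect_length(s5, 2 + 3 + 4 + 5)
  # same seed, same membership; different seed, same accounting
  s5b <- run_sweep(X, 2, 5, max_iter = 100, seed = 1)
  expect_identical(lapply(s5, `[[`, "snp_ids"), lapply(s5b, `[[`, "snp_ids"))
  expect_identical(lapply(s5, `[[`, "subject_ids"),
                   lapply(s5b, `[[`, "subject_ids"))
  s5c <- run_sweep(X, 2, 5, max_iter = 100, seed = 99)
  expect_length(s5c, 14)
})

test_that("degenerate inputs are handled explicitly", {
  X <- matrix(1, 10, 10)
  X[1, ] <- 0  # zero row receives vanishing loadings, no division by zero
  fit <- nsnmf_factorize(X, 2, theta = 0.5, max_iter = 200, seed = 1)
  expect_true(all(is.finite(fit$W)), all(is.finite(fit$H)))
  expect_lt(max(fit$W[1, ]), 1e-6)
  expect_error(nsnmf_factorize(matrix(c(-1, 1, 1, 1), 2), 2), "nonnegative")
  expect_error(nsnmf_factorize(matrix(c(NA, 1, 1, 1), 2), 2), "missing")
})
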