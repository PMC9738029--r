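#' Fit the logistic null model for the kernel association test
#'
#' Logistic regression of disease status on covariates only (iteratively
#' reweighted least squares, tight convergence), storing the fitted
#' probabilities, residuals and variance weights the score test needs.
#'
#' @param y binary status vector, both classes present.
#' @param covariates numeric matrix/data.frame (no intercept column), one row
#'   per subject; `NULL` for an intercept-only null.
#' @param subject_ids optional ids aligned to `y`.
#' @return object of class `skat_null`: `mu`, `resid` (= y - mu), `v`
#'   (= mu(1-mu)), design matrix `X`, `subject_ids`.
#' @export
fit_null <- function(y, covariates = NULL, subject_ids = NULL) {
  stopifnot(all(y %in% 0:1))
  if (length(unique(y)) < 2) stop("y is constant: cannot fit a null model")
  X <- if (is.null(covariates)) matrix(1, length(y), 1)
       else cbind(1, as.matrix(covariates))
  colnames(X)[1] <- "(Intercept)"
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(),
                                         control = stats::glm.control(epsilon = 1e-12,
                                                                      maxit = 100)))
  if (!fit$converged) stop("null model failed to converge")
  mu <- fit$fitted.values
  if (any(mu < 1e-10 | mu > 1 - 1e-10))
    stop("separation detected in the null model (fitted probabilities at 0/1)")
  structure(list(mu = mu, resid = y - mu, v = mu * (1 - mu), X = X, y = y,
                 coef = fit$coefficients,
                 subject_ids = if (is.null(subject_ids)) as.character(seq_along(y))
                               else as.character(subject_ids)),
            class = "skat_null")
}

#' Covariate design for the association tests
#'
#' Age, age squared, sex, BMI, and any ancestry PC columns present; age
#' squared is derived here rather than stored in the phenotype table.
#'
#' @param pheno a [phenotype_table()] (PC columns named `PC1..` are picked up).
#' @return numeric covariate matrix.
#' @export
skat_covariates <- function(pheno) {
  pcs <- grep("^PC[0-9]+$", names(pheno), value = TRUE)
  as.matrix(cbind(age = pheno$age, age2 = pheno$age^2, sex = pheno$sex,
                  bmi = pheno$bmi,
                  as.data.frame(pheno)[, pcs, drop = FALSE]))
}

# Numerical inversion of the characteristic function of sum_j lambda_j chi^2_1:
# P(Q > q) = 1/2 + (1/pi) Int_0^inf sin(theta(u)) / (u rho(u)) du,
# theta(u) = sum_j atan(lambda_j u)/2 - q u/2, rho(u) = prod_j (1 + lambda_j^2 u^2)^(1/4).
# The integrand magnitude is bounded by u^(-1 - p/2) / prod_j sqrt(lambda_j), so
# truncating at U leaves at most (2/p) U^(-p/2) / (pi prod sqrt(lambda)): U is chosen
# from that bound at the requested accuracy and the finite integral evaluated by
# Simpson quadrature resolving the oscillation (~40 nodes per period). When the
# required grid would be infeasibly fine (few, widely spread eigenvalues and a
# slowly decaying tail) the accuracy target is relaxed once; past that the caller
# falls back to the Liu approximation.
davies_p <- function(q, lambda, acc = 1e-9, max_nodes = 2e6) {
  p_n <- length(lambda)
  log_prod_sqrt <- 0.5 * sum(log(lambda))
  for (target in unique(c(acc, 1e-6))) {
    logU <- (log(2 / (p_n * pi * target)) - log_prod_sqrt) * (2 / p_n)
    if (logU > log(1e8)) next
    U <- exp(logU)
    step <- (2 * pi / (0.5 * (q + sum(lambda)))) / 40   # ~40 nodes per oscillation
    npt <- ceiling(U / step)
    if (npt > max_nodes) next
    npt <- max(npt, 200L)
    if (npt %% 2 == 1) npt <- npt + 1L
    h <- U / npt
    vals <- numeric(npt + 1)
    vals[1] <- 0.5 * (sum(lambda) - q)                  # analytic limit at u = 0
    idx <- 2L
    for (chunk in split(seq_len(npt), ceiling(seq_len(npt) / 2e5))) {
      u <- chunk * h
      th <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
      rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
      vals[idx:(idx + length(u) - 1L)] <- sin(th) / (u * rho)
      idx <- idx + length(u)
    }
    int <- h / 3 * (vals[1] + vals[npt + 1] +
                    4 * sum(vals[seq(2, npt, 2)]) + 2 * sum(vals[seq(3, npt - 1, 2)]))
    p <- 0.5 + int / pi
    if (p > 0 && p <= 1) return(p)
  }
  NA_real_
}

# Liu-Tang-Zhang four-moment match to a (non)central chi-square
liu_p <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2); c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0; l <- 1 / s2; a <- sqrt(l)
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  tstar <- (q - mu_q) / sigma_q
  stats::pchisq(tstar * sqrt(2) * a + l + delta, df = l, ncp = delta,
                lower.tail = FALSE)
}

#' Tail probability of a weighted sum of chi-square(1) variables
#'
#' `P(sum_j lambda_j chi^2_1 > q)` by characteristic-function inversion
#' (Davies/Imhof quadrature), falling back to the Liu four-moment
#' approximation when the inversion fails to converge or returns a value
#' outside (0, 1].
#'
#' @param q observed quadratic-form statistic.
#' @param lambda positive mixture weights (eigenvalues).
#' @return list with `p` and `method` (`"davies"` or `"liu"`).
#' @export
mixture_chisq_p <- function(q, lambda) {
  lambda <- lambda[lambda > 0]
  if (!length(lambda) || q <= 0) return(list(p = 1, method = "davies"))
  p <- davies_p(q, lambda)
  if (is.na(p)) list(p = liu_p(q, lambda), method = "liu")
  else list(p = p, method = "davies")
}

#' Kernel association test of one SNP set against a disease
#'
#' Variance-component score test: `Q = (y - mu)' G W^2 G' (y - mu)` over the
#' set's SNP dosage matrix `G` (subjects x SNPs). The set defines only the
#' SNP collection — all subjects in the null model enter the test; subject
#' membership is consumed by the downstream hypergeometric architecture
#' stage. The null distribution of `Q` is the weighted chi-square mixture
#' with weights from the eigenvalues of the covariate-projected kernel.
#'
#' @param s a [snp_set()] (or any object with `$snp_ids` and `$label`).
#' @param g a [genotype_matrix()] containing the set's SNPs; missing dosages
#'   are mean-imputed per SNP for the test.
#' @param null a `skat_null` whose subjects match `g`'s columns.
#' @param weights `"flat"` (w = 1, default: the panel is common variants) or
#'   `"beta"` for Beta(1,25) MAF weights.
#' @return one-row data.frame: `label`, `q_stat`, `p_value`, `method`,
#'   `n_lambda`.
#' @export
skat_test <- function(s, g, null, weights = c("flat", "beta")) {
  weights <- match.arg(weights)
  stopifnot(inherits(null, "skat_null"))
  if (!length(s$snp_ids)) stop("SNP set has no member SNPs")
  idx <- match(s$snp_ids, rownames(g$dosages))
  if (anyNA(idx)) stop("SNP id(s) not in genotype matrix: ",
                       paste(s$snp_ids[is.na(idx)], collapse = ", "))
  ci <- match(null$subject_ids, g$subject_ids)
  if (anyNA(ci)) stop("null-model subjects missing from genotype matrix")
  G <- t(g$dosages[idx, ci, drop = FALSE])          # subjects x SNPs
  storage.mode(G) <- "double"
  for (j in seq_len(ncol(G))) {                     # per-SNP mean imputation
    mj <- is.na(G[, j])
    if (any(mj)) G[mj, j] <- mean(G[, j], na.rm = TRUE)
  }
  w <- if (weights == "flat") rep(1, ncol(G)) else {
    maf <- pmin(colMeans(G) / 2, 1 - colMeans(G) / 2)
    stats::dbeta(maf, 1, 25)
  }
  Gw <- sweep(G, 2, w, "*")
  if (all(Gw == 0))
    return(data.frame(label = s$label, q_stat = 0, p_value = 1,
                      method = "davies", n_lambda = 0L, stringsAsFactors = FALSE))
  sc <- crossprod(Gw, null$resid)
  q <- sum(sc^2)
  # eigenvalues of Gw' P Gw, P = V - V X (X'VX)^-1 X'V
  VG <- Gw * null$v
  VX <- null$X * null$v
  XtVX <- crossprod(null$X, VX)
  M <- crossprod(Gw, VG) - crossprod(crossprod(VX, Gw),
                                     solve(XtVX, crossprod(VX, Gw)))
  lam <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > max(lam) * 1e-10]
  res <- mixture_chisq_p(q, lam)
  data.frame(label = s$label, q_stat = q, p_value = res$p, method = res$method,
             n_lambda = length(lam), stringsAsFactors = FALSE)
}

#' Bonferroni per-test threshold
#' @param alpha family-wise error rate.
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Test all SNP sets against both diseases
#'
#' Each set is tested for CHD and for T2D against nulls adjusted for age,
#' age squared, sex, BMI and any ancestry PCs in the phenotype table. A set
#' is flagged significant when its smaller p-value falls below the
#' Bonferroni threshold over all generated sets; both diseases are tested
#' per set without further correction.
#'
#' @param sets list of [snp_set()] objects (may be empty).
#' @param g a [genotype_matrix()].
#' @param pheno a [phenotype_table()] aligned to `g`'s subjects.
#' @param weights passed to [skat_test()].
#' @param alpha family-wise level for the significance flag.
#' @param n_tests Bonferroni denominator; defaults to `length(sets)`.
#' @return data.frame with one row per set: `label`, `p_chd`, `p_t2d`,
#'   `q_chd`, `q_t2d`, `method_chd`, `method_t2d`, `significant`.
#' @export
test_all_sets <- function(sets, g, pheno, weights = "flat", alpha = 0.05,
                          n_tests = length(sets)) {
  if (!length(sets))
    return(data.frame(label = character(), p_chd = numeric(),
                      p_t2d = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  al <- align_subjects(g, pheno)
  g <- al$genotypes; pheno <- al$phenotypes
  covs <- skat_covariates(pheno)
  null_chd <- fit_null(pheno$chd, covs, pheno$subject_id)
  null_t2d <- fit_null(pheno$t2d, covs, pheno$subject_id)
  thr <- bonferroni_threshold(alpha, n_tests)
  rows <- lapply(sets, function(s) {
    rc <- skat_test(s, g, null_chd, weights)
    rt <- skat_test(s, g, null_t2d, weights)
    data.frame(label = s$label, p_chd = rc$p_value, p_t2d = rt$p_value,
               q_chd = rc$q_stat, q_t2d = rt$q_stat,
               method_chd = rc$method, method_t2d = rt$method,
               significant = min(rc$p_value, rt$p_value) < thr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  out
}
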