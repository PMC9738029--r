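#' Smoothing matrix for nonsmooth NMF
#'
#' `S = (1 - theta) * I + (theta / k) * 1 1'`. At `theta = 0` this is the
#' identity (plain NMF); as `theta` grows toward 1 every factor is pulled
#' toward the uniform vector, which forces sparseness onto `W` and `H`.
#'
#' @param k rank.
#' @param theta smoothness in \[0, 1\].
#' @return k x k smoothing matrix.
#' @export
smoothing_matrix <- function(k, theta) {
  stopifnot(k >= 1, theta >= 0, theta <= 1)
  (1 - theta) * diag(k) + (theta / k) * matrix(1, k, k)
}

kl_divergence <- function(X, Y) {
  # generalized KL: sum(x log(x/y) - x + y), with 0 log 0 = 0
  pos <- X > 0
  sum(X[pos] * log(X[pos] / Y[pos])) - sum(X[pos]) + sum(Y)
}

#' Nonsmooth nonnegative matrix factorization
#'
#' Factorizes a nonnegative matrix as `X ~ W S H` with the smoothing matrix
#' `S(theta)` of [smoothing_matrix()], by multiplicative updates on the
#' generalized Kullback-Leibler divergence (default) or squared Frobenius
#' norm. The `H` update uses the effective basis `W S`, the `W` update the
#' effective coefficients `S H`, so sparseness pressure is transferred to
#' both factors. Denominators are epsilon-guarded; zero rows/columns of `X`
#' simply receive vanishing loadings. `W` columns are normalized to unit sum
#' (with the inverse scale absorbed into `H`) after convergence; the
#' objective trace refers to the raw update sequence, which is provably
#' non-increasing.
#'
#' @param X nonnegative numeric matrix without missing values (impute
#'   upstream, see [encode_matrix()]).
#' @param k rank, `k >= 2`.
#' @param theta smoothness in \[0, 1\] (0 = plain NMF).
#' @param max_iter,tol stopping rule: relative objective change < `tol`, or
#'   `max_iter` iterations.
#' @param seed RNG seed for the uniform random initialization.
#' @param objective `"kl"` or `"frobenius"`.
#' @return object of class `nsnmf_fit`: `W` (rows named as X's rows), `H`
#'   (columns named as X's columns), `theta`, `k`, `objective_trace`,
#'   `seed`, `converged`, `n_iter`.
#' @export
nsnmf_factorize <- function(X, k, theta = 0.5, max_iter = 2000, tol = 1e-6,
                            seed = 1L, objective = c("kl", "frobenius")) {
  objective <- match.arg(objective)
  X <- as.matrix(X)
  if (any(is.na(X))) stop("X contains missing values; impute before factorizing")
  if (any(X < 0)) stop("X must be nonnegative")
  stopifnot(k >= 2, theta >= 0, theta <= 1)
  m <- nrow(X); n <- ncol(X)
  eps <- .Machine$double.eps
  set.seed(seed)
  W <- matrix(stats::runif(m * k, 0.1, 1), m, k)
  H <- matrix(stats::runif(k * n, 0.1, 1), k, n)
  S <- smoothing_matrix(k, theta)
  obj <- function(W, H) {
    Y <- W %*% S %*% H
    if (objective == "kl") kl_divergence(X, Y) else 0.5 * sum((X - Y)^2)
  }
  trace <- numeric(max_iter + 1)
  trace[1] <- obj(W, H)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    A <- W %*% S                                    # effective basis for H-step
    if (objective == "kl") {
      H <- H * (crossprod(A, X / (A %*% H + eps))) / (colSums(A) + eps)
      B <- S %*% H                                  # effective coefficients
      W <- W * ((X / (W %*% B + eps)) %*% t(B)) /
        matrix(rowSums(B) + eps, m, k, byrow = TRUE)
    } else {
      H <- H * (crossprod(A, X)) / (crossprod(A) %*% H + eps)
      B <- S %*% H
      W <- W * (X %*% t(B)) / (W %*% (B %*% t(B)) + eps)
    }
    if (!all(is.finite(W)) || !all(is.finite(H)))
      stop("non-finite values in factors at iteration ", it)
    trace[it + 1] <- obj(W, H)
    denom <- max(trace[it], eps)
    if (abs(trace[it] - trace[it + 1]) / denom < tol) { converged <- TRUE; break }
  }
  trace <- trace[seq_len(it + 1)]
  cs <- colSums(W)
  cs[cs == 0] <- 1                                  # keep zero factors zero
  W <- sweep(W, 2, cs, "/")
  H <- H * cs                                       # scale indeterminacy only
  rownames(W) <- rownames(X)
  colnames(H) <- colnames(X)
  structure(list(W = W, H = H, theta = theta, k = as.integer(k),
                 objective_trace = trace, seed = seed,
                 converged = converged, n_iter = it),
            class = "nsnmf_fit")
}

#' @export
print.nsnmf_fit <- function(x, ...) {
  cat("nsNMF fit: k =", x$k, " theta =", x$theta,
      " iterations =", x$n_iter,
      " final objective =", format(utils::tail(x$objective_trace, 1)),
      if (x$converged) "(converged)\n" else "(max_iter reached)\n")
  invisible(x)
}

#' Encode a genotype matrix for nonnegative factorization
#'
#' `offset_dosage` maps \{0,1,2\} to \{1,2,3\} so homozygous-reference
#' genotypes stay informative under multiplicative updates; `risk_dosage`
#' first reorients each SNP to risk-allele count (protective SNPs flipped
#' `d -> 2 - d` using `snp_meta$risk_direction`) and then offsets. Missing
#' entries are imputed with the per-SNP mode (deterministic, ties to the
#' smaller dosage).
#'
#' @param g a [genotype_matrix()].
#' @param coding `"offset_dosage"` (default) or `"risk_dosage"`.
#' @return numeric matrix with values in \{1,2,3\}, dimnames preserved.
#' @export
encode_matrix <- function(g, coding = c("offset_dosage", "risk_dosage")) {
  coding <- match.arg(coding)
  stopifnot(inherits(g, "genotype_matrix"))
  D <- g$dosages
  if (coding == "risk_dosage") {
    rd <- g$snp_meta$risk_direction
    if (is.null(rd) || anyNA(rd))
      stop("risk_dosage coding requires risk_direction in snp_meta")
    flip <- rd == "protective"
    D[flip, ] <- 2L - D[flip, , drop = FALSE]
  }
  for (i in seq_len(nrow(D))) {
    mi <- is.na(D[i, ])
    if (any(mi)) {
      tab <- tabulate(D[i, !mi] + 1L, nbins = 3L)
      D[i, mi] <- which.max(tab) - 1L               # mode; ties -> smaller dosage
    }
  }
  storage.mode(D) <- "double"
  D + 1
}

#' Extract fuzzy SNP sets from a factorization by relative thresholding
#'
#' In the default `factor_wise` mode SNP `j` belongs to set `i` iff
#' `W[j, i] >= tau * max_j' W[j', i]`, and subject `s` iff
#' `H[i, s] >= tau * max_s' H[i, s']` — 60% of the highest value in each
#' factor by default. `entity_wise` instead thresholds against each SNP's
#' (subject's) own maximum across factors. Both allow multi-membership across
#' sets; `factor_wise` can never produce an empty set (the maximum itself
#' always qualifies), while `entity_wise` factors that end up empty are
#' dropped with a warning.
#'
#' @param fit an `nsnmf_fit`.
#' @param tau relative threshold in (0, 1\].
#' @param mode `"factor_wise"` or `"entity_wise"`.
#' @return list of [snp_set()] objects labeled `G_<k>_<i>`.
#' @export
extract_snp_sets <- function(fit, tau = 0.6, mode = c("factor_wise", "entity_wise")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "nsnmf_fit"), tau > 0, tau <= 1)
  W <- fit$W; H <- fit$H; k <- fit$k
  snp_ids <- rownames(W); subj_ids <- colnames(H)
  if (is.null(snp_ids)) snp_ids <- as.character(seq_len(nrow(W)))
  if (is.null(subj_ids)) subj_ids <- as.character(seq_len(ncol(H)))
  sets <- vector("list", k)
  for (i in seq_len(k)) {
    if (mode == "factor_wise") {
      snps <- which(W[, i] >= tau * max(W[, i]))
      subj <- which(H[i, ] >= tau * max(H[i, ]))
    } else {
      wmax <- apply(W, 1, max); hmax <- apply(H, 2, max)
      snps <- which(W[, i] >= tau * wmax & wmax > 0)
      subj <- which(H[i, ] >= tau * hmax & hmax > 0)
    }
    if (!length(snps) || !length(subj)) {
      warning("factor ", i, " yielded an empty set; dropped")
      next
    }
    sets[[i]] <- snp_set(k, i, snp_ids[snps], subj_ids[subj])
  }
  Filter(Negate(is.null), sets)
}

#' Run the nsNMF rank sweep and collect all SNP sets
#'
#' One factorization per rank `k` in `k_min..k_max`, each extracted with
#' [extract_snp_sets()]; labels `G_k_i` assigned in factor order. Per-rank
#' seeds derive deterministically from the master seed (`seed + 1000 * k`,
#' kept under 2^31). When no factor is dropped the total number of sets is
#' the arithmetic series sum of `k_min..k_max` (135 for 2..16).
#'
#' @param X encoded nonnegative matrix (see [encode_matrix()]).
#' @param k_min,k_max rank range; `k_max` defaults to `floor(sqrt(nrow(X)))`.
#' @param theta,tau,mode,max_iter,tol passed through.
#' @param seed master seed.
#' @param keep_fits if `TRUE`, attach the per-rank fits as an attribute.
#' @return list of [snp_set()] objects across all ranks.
#' @export
run_sweep <- function(X, k_min = 2, k_max = floor(sqrt(nrow(X))), theta = 0.5,
                      tau = 0.6, mode = "factor_wise", max_iter = 2000,
                      tol = 1e-6, seed = 1L, keep_fits = FALSE) {
  stopifnot(k_min >= 2, k_max >= k_min)
  sets <- list()
  fits <- list()
  for (k in k_min:k_max) {
    fit <- nsnmf_factorize(X, k = k, theta = theta, max_iter = max_iter,
                           tol = tol, seed = (seed + 1000L * k) %% .Machine$integer.max)
    sets <- c(sets, extract_snp_sets(fit, tau = tau, mode = mode))
    if (keep_fits) fits[[as.character(k)]] <- fit
  }
  if (keep_fits) attr(sets, "fits") <- fits
  sets
}

#' Write extracted SNP sets as JSON and flat TSV
#'
#' @param sets list of [snp_set()] objects.
#' @param json_path,tsv_path output paths (`NULL` skips that format).
#' @export
write_snp_sets <- function(sets, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    obj <- lapply(sets, function(s) list(label = s$label, k = s$k,
                                         snp_ids = s$snp_ids,
                                         subject_ids = s$subject_ids))
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    rows <- do.call(rbind, lapply(sets, function(s) rbind(
      data.frame(label = s$label, member_type = "snp", member_id = s$snp_ids,
                 stringsAsFactors = FALSE),
      data.frame(label = s$label, member_type = "subject",
                 member_id = s$subject_ids, stringsAsFactors = FALSE))))
    utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
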