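#' Estimate admixture ancestry proportions by EM block ascent
#'
#' Maximizes the binomial admixture log-likelihood
#' `sum_{i,l} d_il log(pi_il) + (2 - d_il) log(1 - pi_il)` with
#' `pi_il = sum_k Q_ik F_kl`, alternating EM updates for the per-sample
#' ancestry proportions `Q` and the per-cluster allele frequencies `F`.
#' Missing dosages are excluded from the likelihood rather than imputed.
#' The likelihood is non-decreasing across iterations; convergence is
#' declared when the improvement falls below `tol`.
#'
#' @param g A [geno_matrix()].
#' @param K Number of ancestral clusters (>= 1). `K = 1` has the closed
#'   form `Q = 1`, `F` = pooled frequencies.
#' @param seed Integer seed for the random initialisation.
#' @param max_iter Maximum EM iterations.
#' @param tol Log-likelihood improvement below which iteration stops.
#' @return An `ancestry_fit` object: `Q` (n x K, rows sum to 1), `F`
#'   (K x n_loci), `loglik` (final value), `loglik_path`, `K`, `seed`,
#'   `converged`, `n_iter`.
#' @export
estimate_ancestry <- function(g, K = 2, seed = 1L, max_iter = 500,
                              tol = 1e-3) {
  stopifnot(inherits(g, "geno_matrix"), K >= 1)
  d <- g$dosages
  m <- !is.na(d)
  dd <- d
  dd[!m] <- 0L
  storage.mode(dd) <- "double"
  mm <- m * 1
  n <- nrow(d); L <- ncol(d)
  eps <- 1e-9

  pooled <- colSums(dd) / pmax(2 * colSums(mm), 1)
  if (K == 1) {
    Fmat <- matrix(pmin(pmax(pooled, eps), 1 - eps), 1, L)
    Q <- matrix(1, n, 1)
    ll <- admixture_loglik(dd, mm, Q, Fmat)
    return(new_ancestry_fit(Q, Fmat, ll, ll, K, seed, TRUE, 0, g))
  }

  set.seed(seed)
  Q <- matrix(stats::rgamma(n * K, 1), n, K)
  Q <- Q / rowSums(Q)
  Fmat <- matrix(pmin(pmax(
    rep(pooled, each = K) + stats::runif(K * L, -0.1, 0.1), 0.01), 0.99),
    K, L)

  ll_path <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  two_minus_d <- (2 - dd) * mm
  d_obs <- dd * mm
  denom_q <- 2 * rowSums(mm)

  for (it in seq_len(max_iter)) {
    P <- Q %*% Fmat
    P <- pmin(pmax(P, eps), 1 - eps)
    ra <- d_obs / P           # d / pi
    rb <- two_minus_d / (1 - P)
    alt_by_k <- matrix(0, K, L)
    ref_by_k <- matrix(0, K, L)
    Qnew <- matrix(0, n, K)
    for (k in seq_len(K)) {
      a_k <- (Q[, k] * ra) * matrix(Fmat[k, ], n, L, byrow = TRUE)
      b_k <- (Q[, k] * rb) * matrix(1 - Fmat[k, ], n, L, byrow = TRUE)
      alt_by_k[k, ] <- colSums(a_k)
      ref_by_k[k, ] <- colSums(b_k)
      Qnew[, k] <- rowSums(a_k) + rowSums(b_k)
    }
    Fmat <- alt_by_k / pmax(alt_by_k + ref_by_k, eps)
    Fmat <- pmin(pmax(Fmat, eps), 1 - eps)
    Q <- Qnew / denom_q
    Q <- Q / rowSums(Q)

    ll <- admixture_loglik(dd, mm, Q, Fmat)
    ll_path <- c(ll_path, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) {
    warning("EM did not converge in ", max_iter, " iterations")
  }
  new_ancestry_fit(Q, Fmat, ll, ll_path, K, seed, converged, length(ll_path), g)
}

admixture_loglik <- function(dd, mm, Q, Fmat, eps = 1e-9) {
  P <- Q %*% Fmat
  P <- pmin(pmax(P, eps), 1 - eps)
  sum(mm * (dd * log(P) + (2 - dd) * log(1 - P)))
}

new_ancestry_fit <- function(Q, Fmat, ll, ll_path, K, seed, converged,
                             n_iter, g) {
  rownames(Q) <- sample_ids(g)
  colnames(Q) <- paste0("K", seq_len(ncol(Q)))
  colnames(Fmat) <- loci(g)$locus_id
  structure(list(Q = Q, F = Fmat, loglik = ll, loglik_path = ll_path,
                 K = K, seed = seed, converged = converged, n_iter = n_iter),
            class = "ancestry_fit")
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat("<ancestry_fit> K =", x$K, ", n =", nrow(x$Q),
      ", loglik =", format(x$loglik), ",",
      if (x$converged) "converged" else "NOT converged",
      "in", x$n_iter, "iterations\n")
  invisible(x)
}

#' Tidy an ancestry fit into long format
#'
#' @param x An `ancestry_fit`.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `cluster`, `proportion`.
#' @export
tidy.ancestry_fit <- function(x, ...) {
  tibble::as_tibble(x$Q, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "cluster",
                        values_to = "proportion")
}

#' @export
glance.ancestry_fit <- function(x, ...) {
  tibble::tibble(K = x$K, loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged, seed = x$seed)
}

#' Align cluster labels between two ancestry matrices
#'
#' Admixture solutions are identified only up to a permutation of cluster
#' labels. This finds, by exhaustive search over permutations (K <= 7), the
#' relabelling of `Q` minimising the mean absolute difference to `Q_ref`.
#'
#' @param Q,Q_ref Matrices with the same shape (samples x K).
#' @return `Q` with columns permuted to best match `Q_ref`; the permutation
#'   is attached as attribute `"perm"`.
#' @export
match_clusters <- function(Q, Q_ref) {
  K <- ncol(Q)
  stopifnot(K <= 7, identical(dim(Q), dim(Q_ref)))
  perms <- perms_of(K)
  costs <- vapply(perms, function(p) mean(abs(Q[, p, drop = FALSE] - Q_ref)), 0)
  best <- perms[[which.min(costs)]]
  out <- Q[, best, drop = FALSE]
  colnames(out) <- colnames(Q_ref)
  attr(out, "perm") <- best
  out
}

perms_of <- function(K) {
  if (K == 1) return(list(1L))
  sub <- perms_of(K - 1)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(K)) {
      out[[length(out) + 1]] <- append(p, K, after = pos - 1)
    }
  }
  out
}

#' Choose K by masked-entry cross-validation
#'
#' For each fold, a random fraction of the non-missing genotype entries is
#' hidden, the admixture model is fit on the remainder, and the squared
#' error between the hidden dosages and their fitted expectation
#' `2 * pi_il` is accumulated. The mean masked-entry error per `K` is
#' returned; lower is better.
#'
#' @param g A [geno_matrix()].
#' @param K_list Integer vector of K values to evaluate.
#' @param mask_fraction Fraction of observed entries hidden per fold, in
#'   (0, 0.5].
#' @param n_folds Number of folds (fresh random masks).
#' @param seed Integer seed; fold masks derive deterministically from it.
#' @param ... Passed to [estimate_ancestry()] (e.g. `max_iter`, `tol`).
#' @return A `cross_val_K` object: tibble `errors` (K, error), `best_K`
#'   (argmin), `mask_fraction`, `fold_seeds`.
#' @export
cross_validate_K <- function(g, K_list = 1:5, mask_fraction = 0.05,
                             n_folds = 10, seed = 1L, ...) {
  stopifnot(mask_fraction > 0, mask_fraction <= 0.5, n_folds >= 1)
  d <- g$dosages
  obs <- which(!is.na(d))
  set.seed(seed)
  fold_seeds <- sample.int(2^31 - 2, n_folds)
  err <- matrix(NA_real_, n_folds, length(K_list),
                dimnames = list(NULL, K_list))
  for (f in seq_len(n_folds)) {
    set.seed(fold_seeds[f])
    masked <- sample(obs, ceiling(mask_fraction * length(obs)))
    d_train <- d
    d_train[masked] <- NA_integer_
    # loci left with no data are skipped in this fold's error
    has_data <- colSums(!is.na(d_train)) > 0
    loci_of <- ((masked - 1) %/% nrow(d)) + 1
    use <- masked[has_data[loci_of]]
    g_train <- geno_matrix(d_train, g$loci, rownames(d))
    for (j in seq_along(K_list)) {
      fit <- suppressWarnings(
        estimate_ancestry(g_train, K = K_list[j], seed = fold_seeds[f], ...))
      P <- fit$Q %*% fit$F
      err[f, j] <- mean((d[use] - 2 * P[use])^2)
    }
  }
  errors <- tibble::tibble(K = K_list, error = colMeans(err))
  structure(list(errors = errors, best_K = K_list[which.min(errors$error)],
                 mask_fraction = mask_fraction, fold_seeds = fold_seeds,
                 per_fold = err),
            class = "cross_val_K")
}

#' @export
print.cross_val_K <- function(x, ...) {
  cat("<cross_val_K> mask", x$mask_fraction, "- best K =", x$best_K, "\n")
  print(x$errors)
  invisible(x)
}

#' Genotype PCA
#'
#' Singular value decomposition of the mean-imputed, column-centred dosage
#' matrix. Loci with no data are dropped (with a message).
#'
#' @param g A [geno_matrix()].
#' @param n_axes Number of leading axes to return scores for.
#' @return A list with `scores` (tibble: sample_id, PC1..), and
#'   `explained_variance` (fractions, non-increasing, summing to <= 1).
#' @export
pca_genotypes <- function(g, n_axes = 10) {
  d <- g$dosages
  if (nrow(d) < 2) stop("need at least 2 samples", call. = FALSE)
  keep <- colSums(!is.na(d)) > 0
  if (!all(keep)) {
    message("pca_genotypes: dropping ", sum(!keep), " all-missing loci")
    d <- d[, keep, drop = FALSE]
  }
  mu <- colMeans(d, na.rm = TRUE)
  x <- sweep(d, 2, mu)
  x[is.na(x)] <- 0   # mean imputation after centring
  sv <- svd(x, nu = min(n_axes, nrow(x) - 1), nv = 0)
  n_axes <- min(n_axes, length(sv$d), nrow(x) - 1)
  scores <- sv$u[, seq_len(n_axes), drop = FALSE] %*%
    diag(sv$d[seq_len(n_axes)], n_axes)
  colnames(scores) <- paste0("PC", seq_len(n_axes))
  ev <- sv$d^2 / sum(sv$d^2)
  list(scores = dplyr::bind_cols(
         tibble::tibble(sample_id = rownames(d)),
         tibble::as_tibble(scores)),
       explained_variance = ev[seq_len(n_axes)])
}

#' Write ancestry results in ADMIXTURE-style layouts
#'
#' `Q` as whitespace-delimited rows (".Q" layout) and `F` transposed to
#' loci x clusters (".P" layout).
#'
#' @param fit An `ancestry_fit`.
#' @param stem Output path stem; writes `<stem>.Q` and `<stem>.P`.
#' @return Paths written, invisibly.
#' @export
write_ancestry <- function(fit, stem) {
  qp <- paste0(stem, ".Q")
  pp <- paste0(stem, ".P")
  utils::write.table(fit$Q, qp, row.names = FALSE, col.names = FALSE)
  utils::write.table(t(fit$F), pp, row.names = FALSE, col.names = FALSE)
  invisible(c(qp, pp))
}
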