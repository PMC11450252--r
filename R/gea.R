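#' Latent factor association scan of genotypes on environment
#'
#' A least-squares latent factor mixed model: `n_latent` factors are
#' estimated from the rank-`n_latent` SVD of the centred (mean-imputed)
#' dosage matrix after projecting off the environmental design with a small
#' ridge penalty; each locus is then regressed on the standardized
#' environmental variables plus the latent factors by ordinary least
#' squares. Per-variable z-scores are recalibrated by genomic-inflation
#' rescaling (the median squared z is forced to the chi-square median), and
#' Benjamini-Hochberg q-values are computed per variable.
#'
#' The scan operates on individual dosages; the partial redundancy analysis
#' ([prda()]) operates on population allele frequencies.
#'
#' @param g A [geno_matrix()], or a numeric samples x loci matrix.
#' @param env Data frame of environmental variables; either one row per
#'   sample in matrix order, or carrying a `sample_id` column to align by.
#'   Non-numeric columns (ids) are dropped from the design.
#' @param n_latent Number of latent factors (0 reduces to plain per-locus
#'   OLS on the environment).
#' @param lambda Ridge penalty used when projecting off the environment
#'   before factor estimation.
#' @param seed Integer seed (kept for interface stability; the fit itself
#'   is deterministic).
#' @return An `lfmm_result`: tibble `stats` (locus_id, variable, beta, z,
#'   p, q), `gif` (per-variable inflation factors), `n_latent`, `factors`.
#' @export
lfmm_scan <- function(g, env, n_latent = 2, lambda = 1e-5, seed = 1L) {
  if (inherits(g, "geno_matrix")) {
    Y <- g$dosages
  } else {
    Y <- as.matrix(g)
  }
  env <- tibble::as_tibble(env)
  if ("sample_id" %in% names(env) && !is.null(rownames(Y))) {
    idx <- match(rownames(Y), env$sample_id)
    if (anyNA(idx)) stop("env rows do not cover all samples", call. = FALSE)
    env <- env[idx, , drop = FALSE]
  }
  X <- as.matrix(env[vapply(env, is.numeric, TRUE)])
  if (nrow(X) != nrow(Y)) {
    stop("env must have one row per sample", call. = FALSE)
  }
  if (n_latent >= min(dim(Y))) {
    stop("n_latent must be < min(n_samples, n_loci)", call. = FALSE)
  }
  X <- scale(X)
  n <- nrow(Y); L <- ncol(Y)

  mu <- colMeans(Y, na.rm = TRUE)
  Yc <- sweep(Y, 2, mu)
  Yc[is.na(Yc)] <- 0

  U <- NULL
  if (n_latent > 0) {
    XtX <- crossprod(X) + diag(lambda, ncol(X))
    R <- Yc - X %*% solve(XtX, crossprod(X, Yc))
    sv <- svd(R, nu = n_latent, nv = 0)
    U <- sv$u %*% diag(sv$d[seq_len(n_latent)], n_latent)
    colnames(U) <- paste0("LF", seq_len(n_latent))
  }

  D <- cbind(`(Intercept)` = 1, X, U)
  q <- ncol(D)
  DtD_inv <- solve(crossprod(D))
  B <- DtD_inv %*% crossprod(D, Yc)
  E <- Yc - D %*% B
  sigma2 <- colSums(E^2) / max(n - q, 1)
  se_scale <- sqrt(diag(DtD_inv))
  vars <- colnames(X)
  locus_ids <- colnames(Y)
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(L))

  rows <- lapply(vars, function(v) {
    j <- match(v, colnames(D))
    beta <- B[j, ]
    se <- se_scale[j] * sqrt(sigma2)
    z <- beta / se
    gif <- stats::median(z^2, na.rm = TRUE) / stats::qchisq(0.5, 1)
    gif <- max(gif, .Machine$double.eps)
    p <- stats::pchisq(z^2 / gif, df = 1, lower.tail = FALSE)
    tibble::tibble(locus_id = locus_ids, variable = v, beta = unname(beta),
                   z = unname(z), p = unname(p),
                   q = unname(stats::p.adjust(p, "BH")), gif = gif)
  })
  stats_tbl <- dplyr::bind_rows(rows)
  gif <- stats_tbl |> dplyr::distinct(.data$variable, .data$gif)
  stats_tbl$gif <- NULL
  structure(list(stats = stats_tbl, gif = gif, n_latent = n_latent,
                 factors = U, seed = seed),
            class = "lfmm_result")
}

#' @export
print.lfmm_result <- function(x, ...) {
  cat("<lfmm_result> ", length(unique(x$stats$locus_id)), " loci x ",
      length(unique(x$stats$variable)), " variables, ", x$n_latent,
      " latent factor(s)\n", sep = "")
  invisible(x)
}

#' @export
tidy.lfmm_result <- function(x, ...) x$stats

#' Candidate loci from a latent factor scan
#'
#' Loci whose smallest q-value over environmental variables falls below the
#' threshold.
#'
#' @param x An `lfmm_result`.
#' @param q_threshold FDR threshold.
#' @return Character vector of locus ids.
#' @export
lfmm_candidates <- function(x, q_threshold = 0.1) {
  x$stats |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(q_min = min(.data$q), .groups = "drop") |>
    dplyr::filter(.data$q_min < q_threshold) |>
    dplyr::pull("locus_id")
}

align_block <- function(freqs, block) {
  block <- tibble::as_tibble(block)
  if ("population_id" %in% names(block)) {
    idx <- match(rownames(freqs), block$population_id)
    if (anyNA(idx)) stop("block rows do not cover all populations",
                         call. = FALSE)
    block <- block[idx, , drop = FALSE]
  }
  as.data.frame(block[vapply(block, is.numeric, TRUE)])
}

#' (Partial) redundancy analysis of allele frequencies on environment
#'
#' Constrained ordination via `vegan::rda()`: the response (population
#' allele frequencies) and the predictors are residualized on the
#' conditioning design by ordinary least squares, and the fitted values of
#' the multivariate regression of residualized response on residualized
#' predictors are eigen-decomposed. Missing frequency cells are
#' mean-imputed (with a message). The overall model p-value comes from a
#' seeded permutation test of the reduced model.
#'
#' @param freqs Populations x loci allele frequency matrix (rownames =
#'   population ids); see [allele_frequencies()].
#' @param env Data frame of predictor variables (aligned by row order or a
#'   `population_id` column).
#' @param condition Optional conditioning data frame (e.g. geographic
#'   coordinates and ancestry `q_west`), same alignment rules.
#' @param permutations Number of permutations for the model test (0 skips
#'   the test).
#' @param seed Integer seed for the permutation test.
#' @return An `rda_scan`: the vegan ordination plus extracted `loadings`
#'   (loci x constrained axes), `env_scores` (biplot scores), `site_scores`,
#'   `eig` (constrained eigenvalues), `total_inertia`,
#'   `constrained_inertia`, `p_value`.
#' @export
prda <- function(freqs, env, condition = NULL, permutations = 999,
                 seed = 1L) {
  Y <- as.matrix(freqs)
  if (anyNA(Y)) {
    n_miss <- sum(is.na(Y))
    mu <- colMeans(Y, na.rm = TRUE)
    idx <- which(is.na(Y), arr.ind = TRUE)
    Y[idx] <- mu[idx[, 2]]
    message("prda: mean-imputed ", n_miss, " missing frequency cell(s)")
    if (anyNA(Y)) stop("loci with no data at all; drop them first",
                       call. = FALSE)
  }
  X <- align_block(Y, env)
  dat <- X
  rhs <- paste(names(X), collapse = " + ")
  if (!is.null(condition)) {
    Z <- align_block(Y, condition)
    names(Z) <- paste0(".cond_", names(Z))
    dat <- cbind(X, Z)
    rhs <- paste0(rhs, " + Condition(",
                  paste(names(Z), collapse = " + "), ")")
  }
  fml <- stats::as.formula(paste("Y ~", rhs))
  environment(fml) <- environment()
  ord <- vegan::rda(fml, data = dat)

  eig <- ord$CCA$eig
  constrained <- if (is.null(ord$CCA)) 0 else ord$CCA$tot.chi
  total <- ord$tot.chi
  loadings <- env_sc <- site_sc <- NULL
  if (!is.null(ord$CCA) && length(eig) > 0) {
    ax <- seq_along(eig)
    loadings <- vegan::scores(ord, choices = ax, display = "species",
                              scaling = 0)
    env_sc <- vegan::scores(ord, choices = ax, display = "bp", scaling = 0)
    site_sc <- vegan::scores(ord, choices = ax, display = "sites",
                             scaling = 0)
  }
  p_value <- NA_real_
  if (permutations > 0 && constrained > 1e-10) {
    set.seed(seed)
    an <- vegan::anova.cca(ord, permutations = permutations)
    p_value <- an$`Pr(>F)`[1]
  }
  structure(list(ord = ord, loadings = loadings, env_scores = env_sc,
                 site_scores = site_sc, eig = eig,
                 total_inertia = total, constrained_inertia = constrained,
                 conditioned = !is.null(condition), p_value = p_value),
            class = "rda_scan")
}

#' @export
print.rda_scan <- function(x, ...) {
  cat("<rda_scan> constrained inertia ", format(x$constrained_inertia),
      " / total ", format(x$total_inertia),
      if (x$conditioned) " (conditioned)" else "",
      if (!is.na(x$p_value)) paste0(", p = ", format(x$p_value)) else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
glance.rda_scan <- function(x, ...) {
  tibble::tibble(constrained_inertia = x$constrained_inertia,
                 total_inertia = x$total_inertia,
                 r_squared = x$constrained_inertia / x$total_inertia,
                 p_value = x$p_value)
}

#' @export
tidy.rda_scan <- function(x, ...) {
  if (is.null(x$loadings)) return(tibble::tibble())
  tibble::as_tibble(x$loadings, rownames = "locus_id") |>
    tidyr::pivot_longer(-"locus_id", names_to = "axis",
                        values_to = "loading")
}

#' Environmental-variable scores on a constrained axis
#'
#' @param x An `rda_scan`.
#' @param axis Constrained axis (default 1).
#' @return Named numeric vector of biplot scores for the axis.
#' @export
env_scores <- function(x, axis = 1) {
  stopifnot(inherits(x, "rda_scan"))
  if (is.null(x$env_scores) || axis > ncol(x$env_scores)) {
    stop("axis ", axis, " not available", call. = FALSE)
  }
  stats::setNames(x$env_scores[, axis], rownames(x$env_scores))
}

#' Partition genetic variance among climate, geography and demography
#'
#' Runs the full redundancy model (all three blocks as constraints) plus
#' the three partial models in which one block is constrained and the other
#' two condition, and derives the bookkeeping: the confounded fraction is
#' the full-model inertia minus the three unique fractions, and the
#' unexplained fraction is total inertia minus the full model.
#'
#' @param freqs Populations x loci allele frequency matrix.
#' @param climate,geography,demography Data frames of the three predictor
#'   blocks (aligned by row order or `population_id`).
#' @param permutations Permutations for per-model tests (0 skips).
#' @param seed Integer seed.
#' @return A `variance_partition` tibble (see [partition_from_inertias()])
#'   with a `p_value` column when permutations are requested.
#' @export
variance_partition <- function(freqs, climate, geography, demography,
                               permutations = 0, seed = 1L) {
  blocks <- list(climate = align_block(as.matrix(freqs), climate),
                 geography = align_block(as.matrix(freqs), geography),
                 demography = align_block(as.matrix(freqs), demography))
  if (any(vapply(blocks, ncol, 0L) == 0)) {
    stop("every block needs at least one numeric variable", call. = FALSE)
  }
  all_pred <- do.call(cbind, unname(blocks))
  full <- prda(freqs, all_pred, condition = NULL,
               permutations = permutations, seed = seed)
  partials <- lapply(names(blocks), function(b) {
    others <- do.call(cbind, unname(blocks[setdiff(names(blocks), b)]))
    prda(freqs, blocks[[b]], condition = others,
         permutations = permutations, seed = seed)
  })
  names(partials) <- names(blocks)
  out <- partition_from_inertias(
    total = full$total_inertia,
    full = full$constrained_inertia,
    climate = partials$climate$constrained_inertia,
    geography = partials$geography$constrained_inertia,
    demography = partials$demography$constrained_inertia
  )
  if (permutations > 0) {
    out$p_value <- c(full$p_value, partials$climate$p_value,
                     partials$geography$p_value,
                     partials$demography$p_value, NA, NA, NA)
  }
  attr(out, "models") <- c(list(full = full), partials)
  out
}

#' Variance-partition bookkeeping from inertias
#'
#' Pure arithmetic layer of the partitioning: given the total inertia, the
#' full-model constrained inertia and the three single-block partial
#' inertias, derives the confounded and unexplained components and the
#' proportion columns. The `total_fraction` column sums to 1 by
#' construction.
#'
#' @param total Total inertia of the response.
#' @param full Constrained inertia of the full model.
#' @param climate,geography,demography Constrained inertias of the three
#'   partial (conditioned) models.
#' @return A `variance_partition` tibble with columns `component`,
#'   `inertia`, `r_squared` (inertia / total), `explainable_fraction`
#'   (inertia / full) and `total_fraction`.
#' @export
partition_from_inertias <- function(total, full, climate, geography,
                                    demography) {
  confounded <- full - (climate + geography + demography)
  unexplained <- total - full
  comp <- c("full", "climate", "geography", "demography", "confounded",
            "unexplained", "total")
  inertia <- c(full, climate, geography, demography, confounded,
               unexplained, total)
  explainable <- c(1, climate / full, geography / full, demography / full,
                   confounded / full, NA, NA)
  out <- tibble::tibble(
    component = comp,
    inertia = inertia,
    r_squared = inertia / total,
    explainable_fraction = explainable,
    total_fraction = inertia / total
  )
  class(out) <- c("variance_partition", class(out))
  out
}

#' Outlier loci by extreme loadings on a constrained axis
#'
#' Flags loci whose loading on the chosen axis lies more than `sd` standard
#' deviations from the mean loading.
#'
#' @param x An `rda_scan`.
#' @param axis Constrained axis to use.
#' @param sd Number of standard deviations (default 2.5).
#' @return A tibble with `locus_id` and `loading` for the outliers.
#' @export
rda_outliers <- function(x, axis = 1, sd = 2.5) {
  if (is.matrix(x)) {
    x <- structure(list(loadings = x), class = "rda_scan")
  }
  stopifnot(inherits(x, "rda_scan"))
  if (is.null(x$loadings) || axis > ncol(x$loadings)) {
    stop("axis ", axis, " not available", call. = FALSE)
  }
  v <- x$loadings[, axis]
  lim <- sd * stats::sd(v)
  out <- abs(v - mean(v)) > lim
  out[is.na(out)] <- FALSE
  tibble::tibble(locus_id = rownames(x$loadings)[out], loading = v[out])
}

#' Combine candidate sets from the latent factor scan and the pRDA
#'
#' @param lfmm_loci,rda_loci Character vectors of candidate locus ids from
#'   the two methods.
#' @return A `candidate_set`: list with `lfmm`, `rda`, `shared`
#'   (intersection) and `combined` (union).
#' @export
combine_candidates <- function(lfmm_loci, rda_loci) {
  lfmm_loci <- unique(as.character(lfmm_loci))
  rda_loci <- unique(as.character(rda_loci))
  structure(list(lfmm = lfmm_loci, rda = rda_loci,
                 shared = intersect(lfmm_loci, rda_loci),
                 combined = union(lfmm_loci, rda_loci)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> lfmm:", length(x$lfmm), " rda:", length(x$rda),
      " shared:", length(x$shared), " combined:", length(x$combined), "\n")
  invisible(x)
}

#' @export
glance.candidate_set <- function(x, ...) {
  tibble::tibble(n_lfmm = length(x$lfmm), n_rda = length(x$rda),
                 n_shared = length(x$shared), n_combined = length(x$combined))
}

#' Strongest environmental association per candidate locus
#'
#' Assigns each locus the environmental variable with the largest absolute
#' correlation to its allele frequencies. Ties break deterministically to
#' the first variable in canonical column order.
#'
#' @param freqs Populations x loci frequency matrix.
#' @param env Data frame of environmental variables (aligned as in
#'   [prda()]).
#' @param loci Locus ids to assign; default all columns of `freqs`.
#' @return A tibble with `locus_id`, `variable`, `correlation`.
#' @export
strongest_variable <- function(freqs, env, loci = colnames(freqs)) {
  Y <- as.matrix(freqs)[, loci, drop = FALSE]
  X <- as.matrix(align_block(as.matrix(freqs), env))
  cors <- suppressWarnings(stats::cor(Y, X, use = "pairwise.complete.obs"))
  cors[is.na(cors)] <- 0
  best <- apply(abs(cors), 1, which.max)  # which.max takes the first on ties
  tibble::tibble(
    locus_id = loci,
    variable = colnames(X)[best],
    correlation = cors[cbind(seq_along(best), best)]
  )
}

#' RDA restricted to putatively adaptive candidate loci
#'
#' Unconditioned redundancy analysis on the candidate locus submatrix; its
#' axis-1 environmental scores feed the genotype-environment index.
#'
#' @param freqs Populations x loci frequency matrix.
#' @param env Data frame of environmental predictors.
#' @param candidates Character vector of candidate locus ids (non-empty).
#' @param ... Passed to [prda()].
#' @return An `rda_scan`.
#' @export
enriched_rda <- function(freqs, env, candidates, ...) {
  candidates <- as.character(candidates)
  if (length(candidates) == 0) stop("empty candidate set", call. = FALSE)
  miss <- setdiff(candidates, colnames(freqs))
  if (length(miss)) {
    stop("candidates absent from frequency matrix: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  prda(as.matrix(freqs)[, candidates, drop = FALSE], env, condition = NULL,
       ...)
}
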