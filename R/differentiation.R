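#' Pairwise Weir-Cockerham Fst between populations
#'
#' The Weir & Cockerham (1984) estimator, as a multi-locus ratio of sums of
#' the variance components a (between populations), b (between individuals
#' within populations) and c (within individuals): for each pair of
#' populations `Fst = sum_l a_l / sum_l (a_l + b_l + c_l)` over loci that
#' are polymorphic within the pair and genotyped in both populations.
#' Missing genotypes are excluded locus by locus.
#'
#' @param g A [geno_matrix()].
#' @param groups Population assignment (vector or metadata table; see
#'   [allele_frequencies()]).
#' @return A `pairwise_fst` object: a symmetric population x population
#'   matrix with zero diagonal (attribute `estimator = "WC84"`). Pairs with
#'   no usable shared locus get `NA` (with a message).
#' @export
pairwise_fst <- function(g, groups) {
  grp <- resolve_groups(g, groups)
  d <- g$dosages
  pops <- sort(unique(grp))
  if (length(pops) < 2) stop("need at least 2 populations", call. = FALSE)

  # per-pop per-locus sufficient statistics
  stats_for <- function(p) {
    rows <- d[grp == p, , drop = FALSE]
    n <- colSums(!is.na(rows))
    list(n = n,
         p = ifelse(n > 0, colSums(rows, na.rm = TRUE) / (2 * n), NA_real_),
         h = ifelse(n > 0, colSums(rows == 1L, na.rm = TRUE) / n, NA_real_))
  }
  st <- lapply(pops, stats_for)
  names(st) <- pops

  fst <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in (i + 1):length(pops)) {
      comp <- wc_pair_components(st[[i]], st[[j]])
      if (is.na(comp$denom) || comp$denom == 0) {
        message("pairwise_fst: no usable locus for ", pops[i], " ~ ", pops[j])
        fst[i, j] <- fst[j, i] <- NA_real_
      } else {
        fst[i, j] <- fst[j, i] <- comp$a / comp$denom
      }
    }
  }
  structure(fst, estimator = "WC84", class = c("pairwise_fst", "matrix"))
}

# Weir & Cockerham (1984) a, b, c summed over usable loci for one pair
wc_pair_components <- function(s1, s2) {
  n1 <- s1$n; n2 <- s2$n
  use <- n1 > 0 & n2 > 0 & (n1 + n2) > 2
  pbar_all <- (n1 * s1$p + n2 * s2$p) / (n1 + n2)
  use <- use & !is.na(pbar_all) & pbar_all > 0 & pbar_all < 1
  if (!any(use)) return(list(a = NA_real_, denom = NA_real_))
  n1 <- n1[use]; n2 <- n2[use]
  p1 <- s1$p[use]; p2 <- s2$p[use]
  h1 <- s1$h[use]; h2 <- s2$h[use]
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2v <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2v - (pbar * (1 - pbar) - ((r - 1) / r) * s2v - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2v -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = sum(a), denom = sum(a + b + cc))
}

#' Tidy a pairwise Fst matrix into long format
#'
#' @param x A `pairwise_fst` matrix.
#' @param ... Unused.
#' @return A tibble with `pop1`, `pop2`, `fst` (each unordered pair once).
#' @export
tidy.pairwise_fst <- function(x, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(pop1 = rownames(m)[idx[, 1]], pop2 = colnames(m)[idx[, 2]],
                 fst = m[idx])
}

#' Population-specific (beta) Fst
#'
#' The Weir & Goudet allele-matching estimator of the divergence of each
#' population from the common ancestral allele pool:
#' `beta_i = (M_i - M_B) / (1 - M_B)`, where `M_i` is the within-population
#' allele-matching proportion (bias-corrected for sample size) and `M_B` the
#' mean between-population matching, each averaged over loci before the
#' ratio is taken. `beta <= 1`; negative values indicate populations less
#' diverged than the average pair.
#'
#' @inheritParams pairwise_fst
#' @return A `pop_specific_fst` tibble with `population_id`, `beta`, plus
#'   attribute `global` (mean beta).
#' @export
population_specific_fst <- function(g, groups) {
  grp <- resolve_groups(g, groups)
  pops <- sort(unique(grp))
  if (length(pops) < 2) {
    stop("population-specific Fst needs >= 2 populations", call. = FALSE)
  }
  d <- g$dosages
  n_mat <- matrix(NA_real_, length(pops), ncol(d))
  p_mat <- matrix(NA_real_, length(pops), ncol(d))
  for (i in seq_along(pops)) {
    rows <- d[grp == pops[i], , drop = FALSE]
    n <- colSums(!is.na(rows))
    n_mat[i, ] <- n
    p_mat[i, ] <- ifelse(n > 0, colSums(rows, na.rm = TRUE) / (2 * n), NA)
  }
  # within-population matching, corrected for sampling without replacement
  m_within <- (2 * n_mat * (p_mat^2 + (1 - p_mat)^2) - 1) / (2 * n_mat - 1)
  m_within[n_mat < 1 | 2 * n_mat - 1 <= 0] <- NA
  m_i <- rowMeans(m_within, na.rm = TRUE)

  # between-population matching, averaged over ordered pairs and loci
  mb_sum <- 0; mb_n <- 0
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in (i + 1):length(pops)) {
      mij <- p_mat[i, ] * p_mat[j, ] + (1 - p_mat[i, ]) * (1 - p_mat[j, ])
      mij <- mij[!is.na(mij)]
      mb_sum <- mb_sum + sum(mij)
      mb_n <- mb_n + length(mij)
    }
  }
  m_b <- mb_sum / mb_n
  beta <- (m_i - m_b) / (1 - m_b)
  out <- tibble::tibble(population_id = pops, beta = beta)
  attr(out, "global") <- mean(beta)
  class(out) <- c("pop_specific_fst", class(out))
  out
}

#' Neighbour-joining tree from a pairwise Fst matrix
#'
#' Saitou-Nei agglomeration via `ape::nj()`. By default the raw Fst values
#' are used as distances; `linearize = TRUE` uses `Fst / (1 - Fst)`.
#' Negative branch lengths are clamped to zero (count reported in a
#' message).
#'
#' @param d A `pairwise_fst` matrix (or any symmetric distance matrix with
#'   zero diagonal).
#' @param linearize Use `Fst/(1-Fst)` instead of raw Fst.
#' @return An unrooted `ape::phylo` tree with populations as tips.
#' @export
nj_tree <- function(d, linearize = FALSE) {
  m <- as.matrix(unclass(d))
  if (nrow(m) < 3) stop("need >= 3 populations for a tree", call. = FALSE)
  if (anyNA(m)) stop("distance matrix has missing cells", call. = FALSE)
  if (linearize) m <- m / (1 - m)
  tree <- ape::nj(m)
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message("nj_tree: clamped ", sum(neg), " negative branch length(s), ",
            "total deficit ", format(sum(tree$edge.length[neg])))
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Double-centred Gram matrix eigendecomposition (`stats::cmdscale`).
#' Axes with non-positive eigenvalues are dropped with a warning if fewer
#' than `n_axes` remain.
#'
#' @param d Symmetric distance matrix with zero diagonal (e.g.
#'   [pairwise_fst()]).
#' @param n_axes Number of axes requested.
#' @return A list with `scores` (tibble: population_id, MDS1..) and
#'   `eig` (all eigenvalues).
#' @export
classical_mds <- function(d, n_axes = 2) {
  m <- as.matrix(unclass(d))
  if (anyNA(m)) stop("distance matrix has missing cells", call. = FALSE)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(m), k = min(n_axes, nrow(m) - 1),
                    eig = TRUE))
  n_pos <- sum(fit$eig > 1e-12)
  if (n_pos < n_axes) {
    warning("only ", n_pos, " positive eigenvalue(s); scores truncated")
  }
  sc <- as.matrix(fit$points)
  k <- min(ncol(sc), max(n_pos, 1), n_axes)
  sc <- sc[, seq_len(k), drop = FALSE]
  colnames(sc) <- paste0("MDS", seq_len(ncol(sc)))
  list(scores = dplyr::bind_cols(
         tibble::tibble(population_id = rownames(m)),
         tibble::as_tibble(sc)),
       eig = fit$eig)
}

#' Write a distance matrix as PHYLIP square format
#'
#' @param d A square distance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  m <- as.matrix(unclass(d))
  lines <- c(sprintf("%5d", nrow(m)),
             vapply(seq_len(nrow(m)), function(i) {
               paste0(formatC(rownames(m)[i], width = -10),
                      paste(sprintf("%.6f", m[i, ]), collapse = " "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
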