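#' Per-population ALT allele frequencies
#'
#' @param g A [geno_matrix()].
#' @param groups Population assignment for each sample: either a vector
#'   aligned with `sample_ids(g)` or a metadata table with `sample_id` and
#'   `population_id` columns.
#' @return A numeric matrix (populations x loci) of ALT allele frequencies;
#'   cells where a population has no genotyped sample are `NA`.
#' @export
allele_frequencies <- function(g, groups) {
  grp <- resolve_groups(g, groups)
  d <- g$dosages
  pops <- sort(unique(grp))
  if (any(table(grp) == 0)) stop("empty population", call. = FALSE)
  freq <- matrix(NA_real_, length(pops), ncol(d),
                 dimnames = list(pops, colnames(d)))
  for (i in seq_along(pops)) {
    rows <- d[grp == pops[i], , drop = FALSE]
    alt <- colSums(rows, na.rm = TRUE)
    n <- 2 * colSums(!is.na(rows))
    freq[i, ] <- ifelse(n > 0, alt / n, NA_real_)
  }
  freq
}

resolve_groups <- function(g, groups) {
  if (is.data.frame(groups)) {
    idx <- match(sample_ids(g), groups$sample_id)
    if (anyNA(idx)) stop("samples missing from metadata", call. = FALSE)
    grp <- as.character(groups$population_id[idx])
  } else {
    if (length(groups) != nrow(g$dosages)) {
      stop("`groups` length must match the number of samples", call. = FALSE)
    }
    grp <- as.character(groups)
  }
  if (anyNA(grp)) stop("every sample needs a population", call. = FALSE)
  grp
}

#' Per-population genetic diversity metrics
#'
#' Computes, per variant site and averaged over sites with data:
#' observed heterozygosity `Ho` (fraction of heterozygotes among genotyped
#' samples), expected heterozygosity `He = 2p(1-p)`, nucleotide diversity at
#' variant sites `Pi = n/(n-1) * 2p(1-p)` (the sample-size-corrected
#' heterozygosity, with `n` the number of non-missing allele copies), and
#' the number of private alleles `Pa` (loci where an allele seen in the
#' focal population is absent from every other population). Values are
#' averaged over variant sites only, so they are comparable between runs of
#' this package, not to genome-wide nucleotide diversity.
#'
#' @inheritParams allele_frequencies
#' @return A tibble with one row per population: `population_id`, `n_samples`,
#'   `Ho`, `He`, `Pi`, `Pa`. Populations with fewer than two genotyped
#'   allele copies at every locus get `NA` for `Pi`.
#' @export
diversity_metrics <- function(g, groups) {
  grp <- resolve_groups(g, groups)
  d <- g$dosages
  pops <- sort(unique(grp))
  freq <- allele_frequencies(g, grp)

  res <- lapply(pops, function(p) {
    rows <- d[grp == p, , drop = FALSE]
    n_geno <- colSums(!is.na(rows))
    n_allele <- 2 * n_geno
    het <- colSums(rows == 1L, na.rm = TRUE)
    ho_site <- ifelse(n_geno > 0, het / n_geno, NA_real_)
    pf <- freq[p, ]
    he_site <- 2 * pf * (1 - pf)
    pi_site <- ifelse(n_allele >= 2,
                      n_allele / (n_allele - 1) * he_site, NA_real_)
    tibble::tibble(
      population_id = p,
      n_samples = sum(grp == p),
      Ho = mean(ho_site, na.rm = TRUE),
      He = mean(he_site, na.rm = TRUE),
      Pi = if (all(is.na(pi_site))) NA_real_ else mean(pi_site, na.rm = TRUE)
    )
  })
  out <- dplyr::bind_rows(res)

  # private alleles: an allele present in the focal population and absent
  # from all other populations (among populations with data at the locus)
  pa <- vapply(seq_along(pops), function(i) {
    others <- freq[-i, , drop = FALSE]
    has_alt <- freq[i, ] > 0
    has_ref <- freq[i, ] < 1
    others_alt <- apply(others, 2, function(x) any(x > 0, na.rm = TRUE))
    others_ref <- apply(others, 2, function(x) any(x < 1, na.rm = TRUE))
    others_any <- colSums(!is.na(others)) > 0
    private <- !is.na(freq[i, ]) & others_any &
      ((has_alt & !others_alt) | (has_ref & !others_ref))
    sum(private)
  }, 0L)
  out$Pa <- pa
  out
}

#' Fit status + ancestry-polynomial models of diversity
#'
#' For each continuous metric (`Ho`, `He`, `Pi`) fits an ordinary linear
#' model `metric ~ status + q_west + q_west^2`; for the private-allele count
#' (`Pa`) a Poisson log-link GLM of the same form. The significance of each
#' fixed effect is assessed by a likelihood-ratio comparison of nested
#' models: an F test for the linear models and a deviance chi-square for
#' the Poisson model. The ancestry term (linear + quadratic, 2 df) and the
#' status term (2 df for three levels) are each dropped jointly. Per-status
#' fitted means with Wald 95% confidence intervals (computed on the link
#' scale for the Poisson model) are reported via `emmeans`.
#'
#' @param div A [diversity_metrics()] table.
#' @param pop_q A data frame with `population_id` and `q_west` (admixture
#'   proportion to the Western cluster) per population.
#' @param status A data frame with `population_id` and `status`, or a vector
#'   aligned with `div$population_id`.
#' @param metrics Which responses to model.
#' @return A named list of `div_model_fit` objects (one per metric), class
#'   `div_model_fits`. Each holds the fitted model, the likelihood-ratio
#'   test table, a fit statistic (R2 or deviance) and per-status means.
#' @export
fit_diversity_models <- function(div, pop_q, status,
                                 metrics = c("Ho", "He", "Pi", "Pa")) {
  dat <- dplyr::left_join(div, tibble::as_tibble(pop_q), by = "population_id")
  if (is.data.frame(status)) {
    dat <- dplyr::left_join(dat, tibble::as_tibble(status),
                            by = "population_id")
  } else {
    dat$status <- status
  }
  if (anyNA(dat$q_west) || anyNA(dat$status)) {
    stop("every population needs q_west and status", call. = FALSE)
  }
  dat$status <- factor(dat$status)
  n_par <- 2 + length(levels(dat$status))  # intercept + q + q^2 + (k-1)
  fits <- lapply(metrics, function(m) {
    sub <- dat[!is.na(dat[[m]]), , drop = FALSE]
    if (nrow(sub) <= n_par) {
      stop("fewer populations than model parameters for ", m, call. = FALSE)
    }
    fit_one_diversity_model(sub, m)
  })
  names(fits) <- metrics
  structure(fits, class = "div_model_fits")
}

fit_one_diversity_model <- function(dat, metric) {
  poisson_fit <- metric == "Pa"
  single_status <- nlevels(droplevels(dat$status)) < 2
  rhs_full <- if (single_status) "q_west + I(q_west^2)"
              else "status + q_west + I(q_west^2)"
  f_full <- stats::as.formula(paste(metric, "~", rhs_full))
  f_no_anc <- stats::as.formula(paste(metric, "~",
                                      if (single_status) "1" else "status"))
  f_no_status <- stats::as.formula(paste(metric, "~ q_west + I(q_west^2)"))

  if (poisson_fit) {
    full <- stats::glm(f_full, data = dat, family = stats::poisson())
    no_anc <- stats::glm(f_no_anc, data = dat, family = stats::poisson())
    tests <- list(ancestry = stats::anova(no_anc, full, test = "Chisq"))
    if (!single_status) {
      no_status <- stats::glm(f_no_status, dat, family = stats::poisson())
      tests$status <- stats::anova(no_status, full, test = "Chisq")
    }
    test_tbl <- dplyr::bind_rows(lapply(names(tests), function(nm) {
      a <- tests[[nm]]
      tibble::tibble(term = nm, df = a$Df[2], statistic = a$Deviance[2],
                     p_value = a$`Pr(>Chi)`[2])
    }))
    stat <- c(deviance = stats::deviance(full))
  } else {
    full <- stats::lm(f_full, data = dat)
    no_anc <- stats::lm(f_no_anc, data = dat)
    tests <- list(ancestry = stats::anova(no_anc, full))
    if (!single_status) {
      no_status <- stats::lm(f_no_status, data = dat)
      tests$status <- stats::anova(no_status, full)
    }
    test_tbl <- dplyr::bind_rows(lapply(names(tests), function(nm) {
      a <- tests[[nm]]
      tibble::tibble(term = nm, df = a$Df[2], statistic = a$F[2],
                     p_value = a$`Pr(>F)`[2])
    }))
    rsq <- summary(full)$r.squared
    # a constant response has no variance to explain
    if (!is.finite(rsq) || stats::var(dat[[metric]]) < 1e-14) rsq <- 0
    stat <- c(r_squared = rsq)
  }

  status_means <- NULL
  if (!single_status) {
    em <- emmeans::emmeans(full, "status",
                           type = if (poisson_fit) "response" else "link")
    es <- as.data.frame(em)
    mean_col <- intersect(c("emmean", "rate", "response"), names(es))[1]
    lcl_col <- intersect(c("lower.CL", "asymp.LCL"), names(es))[1]
    ucl_col <- intersect(c("upper.CL", "asymp.UCL"), names(es))[1]
    status_means <- tibble::tibble(
      status = as.character(es$status),
      mean = es[[mean_col]], lower = es[[lcl_col]], upper = es[[ucl_col]])
  }
  structure(list(response = metric, model = full, tests = test_tbl,
                 statistic = stat, status_means = status_means,
                 data = dat),
            class = "div_model_fit")
}

#' @export
print.div_model_fit <- function(x, ...) {
  cat("<div_model_fit> response:", x$response, "\n")
  print(x$tests)
  invisible(x)
}

#' @export
print.div_model_fits <- function(x, ...) {
  for (f in x) print(f)
  invisible(x)
}

#' Tidy a diversity model fit
#'
#' @param x A `div_model_fit`.
#' @param ... Unused.
#' @return Coefficient table as a tibble (term, estimate, std.error,
#'   statistic, p.value).
#' @export
tidy.div_model_fit <- function(x, ...) {
  co <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(co), estimate = unname(co[, 1]),
                 std.error = unname(co[, 2]), statistic = unname(co[, 3]),
                 p.value = unname(co[, 4]))
}

#' Glance at a diversity model fit
#'
#' @param x A `div_model_fit`.
#' @param ... Unused.
#' @return One-row tibble with the response, fit statistic and the
#'   likelihood-ratio p-values for the ancestry and status terms.
#' @export
glance.div_model_fit <- function(x, ...) {
  p <- stats::setNames(x$tests$p_value, x$tests$term)
  tibble::tibble(
    response = x$response,
    statistic_name = names(x$statistic),
    statistic = unname(x$statistic),
    p_ancestry = unname(p["ancestry"]),
    p_status = unname(p["status"])
  )
}

#' @export
glance.div_model_fits <- function(x, ...) {
  dplyr::bind_rows(lapply(x, glance))
}
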