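test_that("BH q-values agree with a direct step-up implementation", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
  }
  set.seed(1)
  for (r in 1:5) {
    p <- runif(500)^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  # q >= p and q is what the scan reports
  g <- random_geno(40, 100, miss = 0, seed = 2)
  env <- data.frame(matrix(rnorm(40 * 2), 40, 2))
  names(env) <- c("v1", "v2")
  lf <- lfmm_scan(g, env, n_latent = 1)
  expect_true(all(lf$stats$q >= lf$stats$p - 1e-12))
  v1 <- lf$stats[lf$stats$variable == "v1", ]
  expect_equal(v1$q, bh_oracle(v1$p), tolerance = 1e-12)
})

test_that("environment permuted against genotypes gives uniform p-values", {
  cfg <- sim_config(n_native_pops = 30, n_introduced_pops = 0,
                    n_farmed_pops = 0, samples_per_pop = 10, n_loci = 2000,
                    n_adaptive_loci = 40, seed = 2)
  sim <- suppressMessages(simulate_dataset(cfg))
  std <- standardize_env(sim$env)
  es <- dplyr::left_join(sim$meta[, c("sample_id", "population_id")],
                         std$env, by = "population_id")
  set.seed(9)
  Xp <- es[sample(nrow(es)), bioclim_vars]
  Xp$sample_id <- sim$meta$sample_id
  lf <- lfmm_scan(sim$geno, Xp[, c("sample_id", bioclim_vars)], n_latent = 2)
  pv <- lf$stats$p[lf$stats$variable == "AnnMeanTemp"]
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("with no latent factors the scan reduces to per-locus OLS", {
  g <- random_geno(50, 60, miss = 0, seed = 7)
  env <- data.frame(v1 = rnorm(50), v2 = rnorm(50))
  lf <- lfmm_scan(g, env, n_latent = 0)
  X <- scale(as.matrix(env))
  for (l in c(1, 17, 60)) {
    y <- g$dosages[, l] - mean(g$dosages[, l])
    fit <- stats::lm(y ~ X)
    co <- summary(fit)$coefficients
    got <- lf$stats[lf$stats$locus_id == loci(g)$locus_id[l], ]
    expect_equal(got$beta[got$variable == "v1"], co["Xv1", 1],
                 tolerance = 1e-10)
    expect_equal(got$z[got$variable == "v2"], co["Xv2", 3],
                 tolerance = 1e-10)
  }
  expect_error(lfmm_scan(g, env, n_latent = 50), "n_latent")
})

test_that("the scan finds planted environment-associated loci", {
  cfg <- sim_config(n_native_pops = 60, n_introduced_pops = 0,
                    n_farmed_pops = 0, samples_per_pop = 15, n_loci = 500,
                    n_adaptive_loci = 20, env_effect = 1.0, seed = 101)
  sim <- suppressMessages(simulate_dataset(cfg))
  std <- standardize_env(sim$env)
  es <- dplyr::left_join(sim$meta[, c("sample_id", "population_id")],
                         std$env, by = "population_id")
  lf <- lfmm_scan(sim$geno, es[, c("sample_id", bioclim_vars)], n_latent = 2)
  cand <- lfmm_candidates(lf, 0.1)
  truth <- sim$truth$adaptive_locus_ids
  expect_gte(length(intersect(cand, truth)) / length(truth), 0.8)
  expect_lte(length(setdiff(cand, truth)) / max(length(cand), 1), 0.2)
})

test_that("unconditioned RDA equals the textbook fitted-value eigenproblem", {
  set.seed(11)
  n <- 24; L <- 40
  Y <- matrix(rnorm(n * L), n, L)
  colnames(Y) <- paste0("x", 1:L)
  rownames(Y) <- paste0("p", 1:n)
  env <- data.frame(e1 = rnorm(n), e2 = rnorm(n), e3 = rnorm(n))
  fit <- suppressMessages(prda(Y, env, permutations = 0))

  Yc <- scale(Y, scale = FALSE)
  X <- scale(as.matrix(env), scale = FALSE)
  H <- X %*% solve(crossprod(X), t(X))
  fitted <- H %*% Yc
  ev <- svd(fitted / sqrt(n - 1))$d^2
  expect_equal(unname(fit$eig), ev[seq_along(fit$eig)], tolerance = 1e-10)
  expect_equal(fit$total_inertia, sum(diag(stats::cov(Y))),
               tolerance = 1e-10)

  # one predictor: constrained inertia is the multivariate regression
  # R^2 times total inertia, computed directly on a 6 x 10 toy matrix
  Y2 <- matrix(rnorm(60), 6, 10)
  colnames(Y2) <- paste0("y", 1:10); rownames(Y2) <- paste0("p", 1:6)
  x <- rnorm(6)
  fit2 <- suppressMessages(prda(Y2, data.frame(x = x), permutations = 0))
  Y2c <- scale(Y2, scale = FALSE)
  xc <- x - mean(x)
  b <- crossprod(xc, Y2c) / sum(xc^2)
  ss_fit <- sum((xc %*% b)^2)
  expect_equal(fit2$constrained_inertia, ss_fit / (6 - 1), tolerance = 1e-10)
})

test_that("self-conditioning removes all constrained inertia", {
  set.seed(12)
  Y <- matrix(rnorm(20 * 30), 20, 30)
  colnames(Y) <- paste0("x", 1:30); rownames(Y) <- paste0("p", 1:20)
  env <- data.frame(a = rnorm(20), b = rnorm(20))
  fit <- suppressWarnings(suppressMessages(
    prda(Y, env, condition = env, permutations = 0)))
  expect_lt(fit$constrained_inertia / fit$total_inertia, 1e-10)
})

test_that("variance partitioning books inertias consistently", {
  # printed-table bookkeeping: the arithmetic layer reproduces the published
  # decomposition of 1100.3 total / 863.6 explained
  vp <- partition_from_inertias(total = 1100.3, full = 863.6,
                                climate = 61.2, geography = 43.4,
                                demography = 339.3)
  expect_equal(vp$inertia[vp$component == "unexplained"], 236.7,
               tolerance = 1e-9)
  expect_equal(round(vp$r_squared[vp$component == "full"], 3), 0.785)
  expect_equal(round(vp$r_squared[vp$component == "climate"], 3), 0.056)
  expect_equal(round(vp$r_squared[vp$component == "demography"], 3), 0.308)
  parts <- vp$total_fraction[vp$component %in%
    c("climate", "geography", "demography", "confounded", "unexplained")]
  expect_equal(sum(parts), 1, tolerance = 1e-10)

  # orthogonal synthetic blocks leave nothing confounded
  set.seed(13)
  n <- 40
  base <- qr.Q(qr(matrix(rnorm(n * 6), n, 6)))
  clim <- data.frame(c1 = base[, 1], c2 = base[, 2])
  geog <- data.frame(g1 = base[, 3], g2 = base[, 4])
  demo <- data.frame(d1 = base[, 5])
  Y <- 3 * base[, 1] %o% rnorm(30) + 2 * base[, 3] %o% rnorm(30) +
    base[, 5] %o% rnorm(30) + 0.3 * matrix(rnorm(n * 30), n, 30)
  colnames(Y) <- paste0("x", 1:30); rownames(Y) <- paste0("p", 1:n)
  vp2 <- suppressMessages(variance_partition(Y, clim, geog, demo))
  expect_lt(abs(vp2$total_fraction[vp2$component == "confounded"]), 0.02)
  expect_equal(sum(vp2$total_fraction[vp2$component %in%
    c("climate", "geography", "demography", "confounded", "unexplained")]),
    1, tolerance = 1e-10)
  # full-model proportion is full inertia over total on any input
  expect_equal(vp2$r_squared[vp2$component == "full"],
               vp2$inertia[vp2$component == "full"] /
                 vp2$inertia[vp2$component == "total"], tolerance = 1e-12)
})

test_that("structure-only frequencies leave climate with no unique variance", {
  fracs <- vapply(1:5, function(r) {
    cfg <- sim_config(n_native_pops = 60, n_introduced_pops = 0,
                      n_farmed_pops = 0, samples_per_pop = 40, n_loci = 300,
                      n_adaptive_loci = 0, fst_divergence = 0.3,
                      env_effect = 0, seed = 200 + r)
    sim <- suppressMessages(simulate_dataset(cfg))
    std <- standardize_env(sim$env)
    fr <- allele_frequencies(sim$geno, sim$meta)[sim$env$population_id, ]
    coords <- as.data.frame(population_table(sim$meta)[, c("lon", "lat")])
    vp <- suppressMessages(variance_partition(
      fr, std$env[, bioclim_vars], coords,
      data.frame(q_west = sim$truth$pop_q$q_west)))
    vp$r_squared[vp$component == "climate"]
  }, 0)
  expect_lte(mean(fracs), 0.02)
})

test_that("the 2.5-SD loading rule flags the expected Gaussian tail", {
  set.seed(14)
  loadings <- matrix(rnorm(1e4), ncol = 1,
                     dimnames = list(paste0("x", 1:1e4), "RDA1"))
  out <- rda_outliers(loadings, axis = 1, sd = 2.5)
  frac <- nrow(out) / 1e4
  expect_lt(abs(frac - 2 * stats::pnorm(-2.5)), 0.004)
  expect_equal(nrow(rda_outliers(loadings, axis = 1, sd = Inf)), 0L)
})

test_that("candidate set algebra matches inclusion-exclusion", {
  lfmm_set <- paste0("L", 1:357)
  rda_set <- c(paste0("L", 1:122), paste0("M", 1:286))  # 122 shared, 408 total
  cs <- combine_candidates(lfmm_set, rda_set)
  expect_length(cs$shared, 122)
  expect_length(cs$combined, 357 + 408 - 122)
  expect_length(cs$combined, 643)

  dis <- combine_candidates(c("a", "b"), c("c"))
  expect_length(dis$combined, 3)
  expect_length(dis$shared, 0)
  ident <- combine_candidates(c("a", "b"), c("b", "a"))
  expect_setequal(ident$combined, ident$shared)
  expect_setequal(ident$combined, c("a", "b"))
})

test_that("strongest-variable assignment is deterministic under ties", {
  set.seed(15)
  n <- 12
  v <- rnorm(n)
  env <- data.frame(first = v, second = v, third = rnorm(n))
  Y <- cbind(l1 = v + rnorm(n, sd = 0.01),
             l2 = env$third + rnorm(n, sd = 0.01))
  rownames(Y) <- paste0("p", 1:n)
  sv <- strongest_variable(Y, env)
  # l1 ties exactly between `first` and `second`; canonical order wins
  expect_equal(sv$variable[sv$locus_id == "l1"], "first")
  expect_equal(sv$variable[sv$locus_id == "l2"], "third")
})

test_that("enriched RDA on all loci equals the plain RDA and is deterministic", {
  set.seed(16)
  Y <- matrix(rnorm(15 * 25), 15, 25)
  colnames(Y) <- paste0("x", 1:25); rownames(Y) <- paste0("p", 1:15)
  env <- data.frame(e1 = rnorm(15), e2 = rnorm(15))
  plain <- suppressMessages(prda(Y, env, permutations = 0))
  enr <- suppressMessages(enriched_rda(Y, env, colnames(Y),
                                       permutations = 0))
  expect_equal(enr$eig, plain$eig, tolerance = 1e-12)
  enr2 <- suppressMessages(enriched_rda(Y, env, colnames(Y),
                                        permutations = 0))
  expect_identical(env_scores(enr, 1), env_scores(enr2, 1))
  expect_error(enriched_rda(Y, env, character()), "empty candidate")
})

test_that("candidate-restricted RDA explains a larger fraction than all loci", {
  ok <- vapply(1:5, function(r) {
    cfg <- sim_config(n_native_pops = 30, n_introduced_pops = 0,
                      n_farmed_pops = 0, samples_per_pop = 10, n_loci = 400,
                      n_adaptive_loci = 30, env_effect = 1.2, seed = 400 + r)
    sim <- suppressMessages(simulate_dataset(cfg))
    std <- standardize_env(sim$env)
    fr <- allele_frequencies(sim$geno, sim$meta)[sim$env$population_id, ]
    envt <- std$env[, bioclim_vars]
    all_rda <- suppressMessages(prda(fr, envt, permutations = 0))
    er <- suppressMessages(enriched_rda(fr, envt,
                                        sim$truth$adaptive_locus_ids,
                                        permutations = 0))
    er$constrained_inertia / er$total_inertia >
      all_rda$constrained_inertia / all_rda$total_inertia
  }, TRUE)
  expect_true(all(ok))
})

test_that("planted adaptive loci are enriched among RDA outliers", {
  cfg <- sim_config(n_native_pops = 30, n_introduced_pops = 0,
                    n_farmed_pops = 0, samples_per_pop = 10, n_loci = 500,
                    n_adaptive_loci = 25, env_effect = 1.2, seed = 19)
  sim <- suppressMessages(simulate_dataset(cfg))
  std <- standardize_env(sim$env)
  fr <- allele_frequencies(sim$geno, sim$meta)[sim$env$population_id, ]
  coords <- as.data.frame(population_table(sim$meta)[, c("lon", "lat")])
  fit <- suppressMessages(suppressWarnings(prda(
    fr, std$env[, bioclim_vars],
    condition = cbind(coords, q_west = sim$truth$pop_q$q_west),
    permutations = 0)))
  out <- rda_outliers(fit, sd = 2.5)
  truth <- sim$truth$adaptive_locus_ids
  a <- sum(out$locus_id %in% truth)
  b <- length(truth) - a
  c_ <- sum(!out$locus_id %in% truth)
  d_ <- (500 - length(truth)) - c_
  odds <- (a / max(b, 0.5)) / (c_ / d_)
  expect_gt(odds, 5)
})
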