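make_std <- function(means, sds) {
  tibble::tibble(variable = names(means), mean = unname(means),
                 sd = unname(sds[names(means)]))
}

test_that("the adaptive index is the standardized score sum, pixel by pixel", {
  r <- sim_raster(20, 20)
  scores <- c(AnnMeanTemp = 1.2, MinTemp = -0.4, MaxTemp = 0.3,
              TempSeason = 0.1, AnnPrec = -0.9)
  means <- vapply(r$grids, mean, 0)
  sds <- vapply(r$grids, stats::sd, 0)
  std <- make_std(means, sds)
  idx <- adaptive_index(scores, r, std)
  # brute-force per-pixel loop oracle
  for (i in c(1, 7, 20)) {
    for (j in c(2, 11, 20)) {
      want <- sum(vapply(names(scores), function(v) {
        scores[[v]] * (r$grids[[v]][i, j] - means[[v]]) / sds[[v]]
      }, 0))
      expect_equal(idx$index[i, j], want, tolerance = 1e-12)
    }
  }

  # a pixel at the reference means has index 0
  flat <- env_raster(lapply(means, function(m) matrix(m, 2, 2)))
  idx0 <- adaptive_index(scores, flat, std)
  expect_equal(idx0$index, matrix(0, 2, 2), tolerance = 1e-12)

  # one-term sum: score 2.0 at standardized value 1.5 gives 3.0
  r1 <- env_raster(list(v = matrix(10 + 1.5 * 2, 1, 1)))
  idx1 <- adaptive_index(c(v = 2), r1, make_std(c(v = 10), c(v = 2)))
  expect_equal(idx1$index[1, 1], 3)

  # linear in the standardized environment
  r2 <- env_raster(list(v = matrix(c(1, 2, 3, 4), 2, 2)))
  st2 <- make_std(c(v = 0), c(v = 1))
  i1 <- adaptive_index(c(v = 1.5), r2, st2)
  r3 <- env_raster(list(v = 2 * matrix(c(1, 2, 3, 4), 2, 2)))
  i2 <- adaptive_index(c(v = 1.5), r3, st2)
  expect_equal(i2$index, 2 * i1$index, tolerance = 1e-12)

  # nodata propagates; unknown variables error
  r4 <- env_raster(list(v = matrix(c(NA, 1, 2, 3), 2, 2)))
  expect_true(is.na(adaptive_index(c(v = 1), r4, st2)$index[1, 1]))
  expect_error(adaptive_index(c(w = 1), r4, st2), "missing from raster")
})

test_that("nearest native source uses the Fst argmin with a lexicographic tie rule", {
  m <- matrix(0, 4, 4,
              dimnames = list(c("I1", "I2", "N1", "N2"),
                              c("I1", "I2", "N1", "N2")))
  m["I1", "N1"] <- m["N1", "I1"] <- 0.05
  m["I1", "N2"] <- m["N2", "I1"] <- 0.10
  m["I2", "N1"] <- m["N1", "I2"] <- 0.07
  m["I2", "N2"] <- m["N2", "I2"] <- 0.07
  meta <- tibble::tibble(
    population_id = c("I1", "I2", "N1", "N2"),
    status = c("introduced", "introduced", "native", "native"),
    lon = 0.5, lat = 0.5)
  mp <- suppressWarnings(nearest_native_source(m, meta))
  expect_equal(mp$source_population_id[mp$population_id == "I1"], "N1")
  expect_warning(nearest_native_source(m, meta), "tie")
  expect_equal(mp$source_population_id[mp$population_id == "I2"], "N1")

  # single native population receives every introduction
  meta2 <- meta
  meta2$status <- c("introduced", "introduced", "native", "farmed")
  mp2 <- nearest_native_source(m, meta2)
  expect_equal(unique(mp2$source_population_id), "N1")
})

test_that("introductions cloned into known sources are recovered from Fst", {
  hits <- vapply(c(3, 11, 42), function(seed) {
    cfg <- sim_config(n_native_pops = 6, n_introduced_pops = 12,
                      n_farmed_pops = 0, samples_per_pop = 15, n_loci = 1500,
                      n_adaptive_loci = 0, founder_size = 100,
                      missing_rate = 0.02, seed = seed)
    sim <- suppressMessages(simulate_dataset(cfg))
    mp <- nearest_native_source(pairwise_fst(sim$geno, sim$meta),
                                population_table(sim$meta))
    tr <- sim$truth$sources
    mean(mp$source_population_id ==
           tr$source_population_id[match(mp$population_id,
                                         tr$population_id)])
  }, 0)
  expect_gte(mean(hits), 0.95)
})

test_that("offsets are absolute index differences with reflection invariance", {
  r <- sim_raster(10, 10)
  means <- vapply(r$grids, mean, 0)
  sds <- vapply(r$grids, stats::sd, 0)
  std <- make_std(means, sds)
  scores <- c(AnnMeanTemp = 1, MinTemp = 0.5, MaxTemp = -0.2,
              TempSeason = 0.3, AnnPrec = -0.6)
  idx <- adaptive_index(scores, r, std)
  meta <- tibble::tibble(
    population_id = c("I1", "I2", "N1"),
    status = c("introduced", "introduced", "native"),
    lon = c(0.15, 0.85, 0.15), lat = c(0.35, 0.65, 0.35))
  mapping <- tibble::tibble(population_id = c("I1", "I2"),
                            source_population_id = "N1")
  off <- genetic_offset(idx, mapping, meta)
  # same pixel as the source: offset exactly 0
  expect_equal(off$offset[off$population_id == "I1"], 0)
  expect_true(all(off$offset >= 0))
  # flipping the axis sign leaves the absolute offset unchanged
  idx_flip <- adaptive_index(-scores, r, std)
  off_flip <- genetic_offset(idx_flip, mapping, meta)
  expect_equal(off_flip$offset, off$offset, tolerance = 1e-12)
  expect_equal(off_flip$offset_signed, -off$offset_signed, tolerance = 1e-12)

  # the offset is a pseudometric between pixels: |a-c| <= |a-b| + |b-c|
  v <- index_at(idx, c(0.1, 0.5, 0.9), c(0.2, 0.5, 0.8))
  expect_lte(abs(v[1] - v[3]),
             abs(v[1] - v[2]) + abs(v[2] - v[3]) + 1e-12)
})

test_that("environment-mismatched introductions receive larger offsets", {
  off_all <- list()
  for (r in 1:10) {
    cfg <- sim_config(n_native_pops = 12, n_introduced_pops = 16,
                      n_farmed_pops = 0, samples_per_pop = 10, n_loci = 500,
                      n_adaptive_loci = 40, env_effect = 1.2,
                      founder_size = 50, seed = 500 + r)
    sim <- suppressMessages(simulate_dataset(cfg))
    nat <- unique(sim$meta$population_id[sim$meta$status == "native"])
    natm <- sim$meta[sim$meta$status == "native", ]
    gn <- subset_geno(sim$geno,
                      samples = sample_ids(sim$geno) %in% natm$sample_id)
    std <- standardize_env(sim$env, sim$env$population_id %in% nat)
    fr <- allele_frequencies(gn, natm)[nat, ]
    envt <- std$env[match(nat, std$env$population_id), bioclim_vars]
    er <- suppressMessages(enriched_rda(fr, envt,
                                        sim$truth$adaptive_locus_ids,
                                        permutations = 0))
    idx <- adaptive_index(env_scores(er, 1), sim$raster,
                          std$standardization)
    pops <- population_table(sim$meta)
    mapping <- sim$truth$sources
    names(mapping)[1] <- "population_id"
    off <- genetic_offset(idx, mapping, pops)
    at <- function(ids, var) raster_extract(
      sim$raster, pops$lon[match(ids, pops$population_id)],
      pops$lat[match(ids, pops$population_id)])[[var]]
    envd <- abs(at(off$population_id, "AnnMeanTemp") -
                  at(off$source_population_id, "AnnMeanTemp"))
    off_all[[r]] <- tibble::tibble(offset = off$offset,
                                   matched = envd < stats::median(envd))
  }
  pooled <- dplyr::bind_rows(off_all)
  p <- stats::wilcox.test(pooled$offset[pooled$matched],
                          pooled$offset[!pooled$matched],
                          alternative = "less")$p.value
  expect_lt(p, 0.01)
})

test_that("offset classification follows tertiles, fixed breaks and tie rules", {
  lab <- classify_offsets(1:9)
  expect_equal(as.vector(table(lab)), c(3L, 3L, 3L))
  expect_equal(as.character(lab[1:3]), rep("Low", 3))

  # fixed breaks against direct comparison
  x <- c(0.5, 2.9, 3.143, 4.0, 5.817, 6.2)
  lab2 <- classify_offsets(x, mode = "fixed", breaks = c(3.143, 5.817))
  want <- ifelse(x <= 3.143, "Low", ifelse(x <= 5.817, "Medium", "High"))
  expect_equal(as.character(lab2), want)
  expect_error(classify_offsets(x, mode = "fixed", breaks = c(5, 1)),
               "breaks")

  expect_warning(lab3 <- classify_offsets(rep(2, 5)), "all offsets equal")
  expect_equal(as.character(lab3), rep("Low", 5))
})

test_that("counting below a threshold matches the published offset table", {
  tab <- tench_offsets()
  expect_equal(nrow(tab), 40L)
  expect_equal(count_below(tab$offset, 2.83), 27L)
  expect_equal(count_below(tab$offset, 0), 0L)
  expect_equal(count_below(tab$offset, Inf), 40L)
})
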