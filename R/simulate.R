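#' Configuration for the synthetic invasion-genomics dataset
#'
#' Defaults emulate the study system the package targets: 36 native, 40
#' introduced and 19 farmed populations; two divergent ancestral clusters
#' (Eastern/Western refugia analogues) with a longitudinal admixture cline
#' across the native range; environment-correlated adaptive loci; and
#' introduced populations founded by small samples from native sources.
#'
#' @param n_native_pops,n_introduced_pops,n_farmed_pops Population counts.
#' @param samples_per_pop Diploid samples per population.
#' @param n_loci Number of biallelic SNP loci (one SNP per RAD locus).
#' @param n_adaptive_loci Number of loci whose frequency tracks the focal
#'   environmental variable.
#' @param fst_divergence Balding-Nichols F for the two ancestral clusters:
#'   cluster allele frequencies are drawn from Beta distributions whose
#'   variance around the ancestral frequency scales with F.
#' @param cline Per-native-population admixture proportion to the Western
#'   cluster, `q_W` in `[0, 1]`; default an even cline from 0 to 1.
#' @param env_effect Slope (logit scale) linking the standardized focal
#'   environmental variable to adaptive-locus allele frequency.
#' @param founder_size Diploid founders per introduction event.
#' @param missing_rate Uniform genotype missingness rate.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_native_pops = 36, n_introduced_pops = 40,
                       n_farmed_pops = 19, samples_per_pop = 7,
                       n_loci = 7958, n_adaptive_loci = 120,
                       fst_divergence = 0.15, cline = NULL,
                       env_effect = 1.0, founder_size = 10,
                       missing_rate = 0.0642, seed = 1L) {
  stopifnot(n_native_pops > 0, n_introduced_pops >= 0, n_farmed_pops >= 0,
            samples_per_pop > 0, n_loci > 0, n_adaptive_loci >= 0,
            fst_divergence > 0, fst_divergence < 1,
            founder_size >= 1, missing_rate >= 0, missing_rate < 1)
  if (n_adaptive_loci > n_loci) {
    stop("more adaptive loci than total loci", call. = FALSE)
  }
  if (is.null(cline)) {
    cline <- if (n_native_pops == 1) 0.5 else
      seq(0, 1, length.out = n_native_pops)
  }
  stopifnot(length(cline) == n_native_pops, all(cline >= 0 & cline <= 1))
  structure(list(n_native_pops = n_native_pops,
                 n_introduced_pops = n_introduced_pops,
                 n_farmed_pops = n_farmed_pops,
                 samples_per_pop = samples_per_pop,
                 n_loci = n_loci, n_adaptive_loci = n_adaptive_loci,
                 fst_divergence = fst_divergence, cline = cline,
                 env_effect = env_effect, founder_size = founder_size,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Build the synthetic environmental raster
#'
#' Five smooth layers (linear trends plus sinusoids) over a unit-square
#' landscape, so that index extrapolation is visually and numerically
#' checkable. The focal adaptive variable (AnnMeanTemp) varies both along
#' the admixture cline axis (x) and across it (y), which reproduces the
#' partial confounding of climate with demographic structure that the
#' variance partitioning stage is designed to expose.
#'
#' @param nrow,ncol Grid shape.
#' @param seed Unused placeholder for interface symmetry; the raster is
#'   deterministic.
#' @return An [env_raster()] with layers [bioclim_vars] on a unit square.
#' @export
sim_raster <- function(nrow = 50, ncol = 50, seed = NULL) {
  xs <- (seq_len(ncol) - 0.5) / ncol
  ys <- 1 - (seq_len(nrow) - 0.5) / nrow   # row 1 = top = max y
  grid_x <- matrix(xs, nrow, ncol, byrow = TRUE)
  grid_y <- matrix(ys, nrow, ncol)
  grids <- list(
    AnnMeanTemp = 8 + 6 * grid_x + 5 * sin(4 * pi * grid_y),
    MinTemp     = -10 + 8 * grid_y,
    MaxTemp     = 20 + 5 * sin(2 * pi * grid_x),
    TempSeason  = 18 + 6 * cos(2 * pi * grid_y),
    AnnPrec     = 700 + 250 * sin(2 * pi * grid_x + 1) + 100 * grid_y
  )
  env_raster(grids, xmin = 0, ymin = 0, cellsize = 1 / max(nrow, ncol))
}

#' Simulate a full invasion-genomics dataset
#'
#' Generates genotypes, sample metadata, a per-population environment table,
#' an environmental raster and the ground truth needed for parameter
#' recovery tests. The generative model:
#' * neutral loci: ancestral frequency `p0 ~ U(0.05, 0.95)`; two cluster
#'   frequencies `p_E, p_W ~ Balding-Nichols(p0, F)`; the frequency in a
#'   native population with Western ancestry `q_W` is
#'   `q_W * p_W + (1 - q_W) * p_E`;
#' * adaptive loci additionally receive a logit-scale shift of
#'   `env_effect` times the standardized focal environmental variable
#'   (AnnMeanTemp) at the population's location;
#' * farmed populations follow the native model with a random `q_W`;
#' * introduced populations are founded by `2 * founder_size` gene copies
#'   drawn binomially from a named native source population, after which
#'   resident genotypes are binomial draws from the founder frequencies;
#' * genotypes are `Binomial(2, p)` dosages; missingness is applied
#'   uniformly at `missing_rate`.
#'
#' A single seed drives the run; independent stage seeds (raster,
#' frequencies, genotypes, missingness) are split from it and recorded in
#' the returned truth object so stages can be re-simulated independently.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `geno` ([geno_matrix()]), `meta` (sample
#'   metadata tibble), `env` (per-population environment table), `raster`
#'   ([env_raster()]) and `truth` (list: `true_q`, `pop_q`,
#'   `adaptive_locus_ids`, `sources`, `focal_var`, `stage_seeds`).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  stage_seeds <- sample.int(2^31 - 2, 4)
  names(stage_seeds) <- c("coords", "freqs", "genotypes", "missing")

  raster <- sim_raster()

  # --- populations and coordinates ----------------------------------------
  set.seed(stage_seeds[["coords"]])
  native_ids <- sprintf("NAT%02d", seq_len(cfg$n_native_pops))
  intro_ids <- if (cfg$n_introduced_pops > 0)
    sprintf("INT%02d", seq_len(cfg$n_introduced_pops)) else character()
  farm_ids <- if (cfg$n_farmed_pops > 0)
    sprintf("FRM%02d", seq_len(cfg$n_farmed_pops)) else character()

  jitter_in <- function(n) stats::runif(n, 0.05, 0.95)
  # cline runs west->east in x; jitter keeps geography informative but not
  # perfectly collinear with ancestry
  native_lon <- pmin(pmax(
    0.02 + 0.96 * cfg$cline +
      stats::runif(cfg$n_native_pops, -0.05, 0.05), 0.005), 0.995)
  native_lat <- jitter_in(cfg$n_native_pops)
  intro_lon <- jitter_in(cfg$n_introduced_pops)
  intro_lat <- jitter_in(cfg$n_introduced_pops)
  farm_lon <- jitter_in(cfg$n_farmed_pops)
  farm_lat <- jitter_in(cfg$n_farmed_pops)
  farm_q <- stats::runif(cfg$n_farmed_pops)
  sources <- if (cfg$n_introduced_pops > 0)
    sample(native_ids, cfg$n_introduced_pops, replace = TRUE) else character()

  pops <- tibble::tibble(
    population_id = c(native_ids, intro_ids, farm_ids),
    status = rep(c("native", "introduced", "farmed"),
                 c(cfg$n_native_pops, cfg$n_introduced_pops,
                   cfg$n_farmed_pops)),
    lon = c(native_lon, intro_lon, farm_lon),
    lat = c(native_lat, intro_lat, farm_lat)
  )
  env_vals <- raster_extract(raster, pops$lon, pops$lat)
  env <- dplyr::bind_cols(pops["population_id"], env_vals)

  # standardized focal variable over native populations
  native_rows <- pops$status == "native"
  focal <- env$AnnMeanTemp
  z_focal <- (focal - mean(focal[native_rows])) / stats::sd(focal[native_rows])

  # --- allele frequencies --------------------------------------------------
  set.seed(stage_seeds[["freqs"]])
  L <- cfg$n_loci
  Fdiv <- cfg$fst_divergence
  p0 <- stats::runif(L, 0.05, 0.95)
  shape_scale <- (1 - Fdiv) / Fdiv
  p_east <- stats::rbeta(L, p0 * shape_scale, (1 - p0) * shape_scale)
  p_west <- stats::rbeta(L, p0 * shape_scale, (1 - p0) * shape_scale)
  adaptive_idx <- if (cfg$n_adaptive_loci > 0)
    sample.int(L, cfg$n_adaptive_loci) else integer()

  clamp <- function(p, eps = 1e-3) pmin(pmax(p, eps), 1 - eps)
  pop_freq <- function(q_w, z_env) {
    p <- clamp(q_w * p_west + (1 - q_w) * p_east)
    if (length(adaptive_idx)) {
      p[adaptive_idx] <- stats::plogis(
        stats::qlogis(p[adaptive_idx]) + cfg$env_effect * z_env)
    }
    p
  }

  q_by_pop <- c(cfg$cline, rep(NA_real_, cfg$n_introduced_pops), farm_q)
  names(q_by_pop) <- pops$population_id
  freq_by_pop <- matrix(NA_real_, nrow(pops), L,
                        dimnames = list(pops$population_id, NULL))
  for (i in which(pops$status != "introduced")) {
    freq_by_pop[i, ] <- pop_freq(q_by_pop[i], z_focal[i])
  }

  # --- founder events for introduced populations --------------------------
  set.seed(stage_seeds[["genotypes"]])
  n_copies <- 2L * cfg$founder_size
  for (i in which(pops$status == "introduced")) {
    src <- sources[match(pops$population_id[i], intro_ids)]
    p_src <- freq_by_pop[src, ]
    freq_by_pop[i, ] <- stats::rbinom(L, n_copies, p_src) / n_copies
    q_by_pop[i] <- q_by_pop[src]
  }

  # --- genotypes -----------------------------------------------------------
  n_pop <- nrow(pops)
  n_samp <- n_pop * cfg$samples_per_pop
  d <- matrix(NA_integer_, n_samp, L)
  sample_pop <- rep(pops$population_id, each = cfg$samples_per_pop)
  for (i in seq_len(n_pop)) {
    rows <- ((i - 1) * cfg$samples_per_pop + 1):(i * cfg$samples_per_pop)
    d[rows, ] <- matrix(
      stats::rbinom(cfg$samples_per_pop * L, 2, rep(freq_by_pop[i, ],
                                                    each = cfg$samples_per_pop)),
      nrow = cfg$samples_per_pop)
  }
  sample_id <- paste0(sample_pop, "_", rep(seq_len(cfg$samples_per_pop), n_pop))

  set.seed(stage_seeds[["missing"]])
  if (cfg$missing_rate > 0) {
    d[stats::runif(length(d)) < cfg$missing_rate] <- NA_integer_
  }

  tags <- sprintf("L%05d", seq_len(L))
  tab <- tibble::tibble(
    locus_id = paste0(tags, ":1"), locus_tag = tags, snp_column = 1L,
    chrom = tags, pos = 1L, ref = "A", alt = "T")
  g <- geno_matrix(d, tab, sample_id)

  meta <- tibble::tibble(
    sample_id = sample_id,
    population_id = sample_pop,
    status = rep(pops$status, each = cfg$samples_per_pop),
    lon = rep(pops$lon, each = cfg$samples_per_pop),
    lat = rep(pops$lat, each = cfg$samples_per_pop)
  )

  truth <- list(
    true_q = tibble::tibble(sample_id = sample_id,
                            q_west = unname(q_by_pop[sample_pop])),
    pop_q = tibble::tibble(population_id = pops$population_id,
                           q_west = unname(q_by_pop)),
    adaptive_locus_ids = tab$locus_id[sort(adaptive_idx)],
    sources = tibble::tibble(population_id = intro_ids,
                             source_population_id = sources),
    focal_var = "AnnMeanTemp",
    cluster_freqs = rbind(east = p_east, west = p_west),
    pop_freqs = freq_by_pop,
    stage_seeds = stage_seeds
  )
  list(geno = g, meta = meta, env = env, raster = raster, truth = truth)
}

#' Expected heterozygosity retention after a founder event
#'
#' The classical drift expectation: a founder population of `n` diploids
#' retains, in expectation, a fraction `1 - 1/(2n)` of the source
#' population's heterozygosity.
#'
#' @param founder_size Number of diploid founders (>= 1).
#' @return The expected retained fraction of heterozygosity.
#' @export
expected_founder_retention <- function(founder_size) {
  if (any(founder_size < 1)) stop("founder_size must be >= 1", call. = FALSE)
  1 - 1 / (2 * founder_size)
}

#' Simulate heterozygosity retention across replicate founder events
#'
#' Draws source allele frequencies uniformly on loci with minor allele
#' frequency above `maf_min`, founds each replicate population with
#' `2 * founder_size` binomially sampled gene copies, and reports the mean
#' over events of mean(He founder)/mean(He source).
#'
#' @param founder_size Diploid founders per event.
#' @param n_loci Loci per event.
#' @param n_events Replicate founder events.
#' @param maf_min Lower bound on the source minor allele frequency.
#' @param seed Integer seed.
#' @return A list with `mean_retention`, per-event `retention`, and the
#'   analytic `expected` value.
#' @export
simulate_founder_retention <- function(founder_size = 10, n_loci = 500,
                                       n_events = 200, maf_min = 0.05,
                                       seed = 1L) {
  stopifnot(founder_size >= 1, n_loci > 0, n_events > 0)
  set.seed(seed)
  n_copies <- 2L * founder_size
  retention <- vapply(seq_len(n_events), function(e) {
    p <- stats::runif(n_loci, maf_min + 1e-6, 1 - maf_min - 1e-6)
    he_src <- 2 * p * (1 - p)
    pf <- stats::rbinom(n_loci, n_copies, p) / n_copies
    he_f <- 2 * pf * (1 - pf)
    mean(he_f) / mean(he_src)
  }, 0)
  list(mean_retention = mean(retention), retention = retention,
       expected = expected_founder_retention(founder_size))
}

#' Write a simulated dataset to disk in the formats the readers consume
#'
#' Emits `genotypes.vcf`, `metadata.tsv`, `env.tsv` and one ASCII grid per
#' raster layer under `dir/rasters/`.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vcf <- file.path(dir, "genotypes.vcf")
  write_vcf(sim$geno, vcf)
  meta <- file.path(dir, "metadata.tsv")
  utils::write.table(sim$meta, meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  env <- file.path(dir, "env.tsv")
  utils::write.table(sim$env, env, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rasters <- write_raster_stack(sim$raster, file.path(dir, "rasters"))
  invisible(list(vcf = vcf, metadata = meta, env = env, rasters = rasters))
}
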