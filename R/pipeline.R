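#' Run the full invasion-genomics pipeline
#'
#' Executes the stages in dependency order — filter, diversity, structure,
#' differentiation, genotype-environment association, offset — from either
#' a simulation config or input paths, writing delimited outputs and a YAML
#' run manifest when `outdir` is given.
#'
#' @param config A named list (or path to a YAML file) with blocks:
#'   * `simulate`: arguments for [sim_config()] (mutually exclusive with
#'     `inputs`);
#'   * `inputs`: `vcf`, `metadata`, `env`, `rasters` (named paths);
#'   * `filter`: arguments for [filter_config()];
#'   * `structure`: `K` (default 2), `seed`;
#'   * `gea`: `n_latent`, `sd_threshold`, `permutations`, `q_threshold`,
#'     `candidate_mode` ("union" or "intersection");
#'   * `offset`: `mode`, `breaks`;
#'   * `outdir`: output directory (optional).
#' @param seed Global seed, used where a block does not set its own.
#' @return A named list of stage results (`geno`, `meta`, `env`, `raster`,
#'   `diversity`, `models`, `ancestry`, `pca`, `fst`, `beta_fst`, `tree`,
#'   `mds`, `lfmm`, `prda`, `partition`, `candidates`, `enriched`, `index`,
#'   `offsets`, `manifest`), invisibly.
#' @export
run_pipeline <- function(config = list(), seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  blk <- function(name) config[[name]] %||% list()

  if (!is.null(config$inputs) && !is.null(config$simulate)) {
    stop("config must use exactly one of `inputs` or `simulate`",
         call. = FALSE)
  }

  # --- inputs ---------------------------------------------------------------
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (p in c("vcf", "metadata", "env")) {
      if (is.null(inp[[p]]) || !file.exists(inp[[p]])) {
        stop("missing input file for `", p, "`: ",
             inp[[p]] %||% "<unset>", call. = FALSE)
      }
    }
    g <- read_vcf(inp$vcf)
    meta <- sample_metadata(
      tibble::as_tibble(utils::read.delim(inp$metadata)), g)
    env <- read_env_table(inp$env)
    raster <- if (!is.null(inp$rasters)) read_raster_stack(unlist(inp$rasters))
              else NULL
    truth <- NULL
  } else {
    scfg <- do.call(sim_config, utils::modifyList(list(seed = seed),
                                                  blk("simulate")))
    sim <- simulate_dataset(scfg)
    g <- sim$geno; meta <- sim$meta; env <- sim$env; raster <- sim$raster
    truth <- sim$truth
  }

  # --- filter ---------------------------------------------------------------
  fcfg <- do.call(filter_config, blk("filter"))
  g <- apply_filters(g, fcfg)
  meta <- meta[meta$sample_id %in% sample_ids(g), ]

  # --- structure ------------------------------------------------------------
  scfg <- blk("structure")
  K <- scfg$K %||% 2
  anc <- estimate_ancestry(g, K = K, seed = scfg$seed %||% seed)
  pca <- pca_genotypes(g, n_axes = 4)
  pops <- population_table(meta)
  q_west <- tibble::tibble(
    population_id = meta$population_id,
    q = anc$Q[match(meta$sample_id, rownames(anc$Q)), K]) |>
    dplyr::group_by(.data$population_id) |>
    dplyr::summarise(q_west = mean(.data$q), .groups = "drop")

  # --- diversity ------------------------------------------------------------
  div <- diversity_metrics(g, meta)
  models <- fit_diversity_models(div, q_west, pops[c("population_id",
                                                     "status")])

  # --- differentiation ------------------------------------------------------
  fst <- pairwise_fst(g, meta)
  beta <- population_specific_fst(g, meta)
  tree <- if (nrow(pops) >= 3 && !anyNA(unclass(fst))) nj_tree(fst) else NULL
  mds <- if (!anyNA(unclass(fst))) classical_mds(fst) else NULL

  # --- genotype-environment association (native range) ----------------------
  gcfg <- blk("gea")
  native_pops <- pops$population_id[pops$status == "native"]
  native_meta <- meta[meta$population_id %in% native_pops, ]
  g_native <- subset_geno(g, samples = sample_ids(g) %in%
                            native_meta$sample_id)
  std <- standardize_env(env, env$population_id %in% native_pops)
  env_std <- std$env
  env_native <- env_std[match(native_pops, env_std$population_id), ]

  env_by_sample <- dplyr::left_join(
    native_meta[, c("sample_id", "population_id")], env_std,
    by = "population_id")
  lfmm <- lfmm_scan(g_native, env_by_sample[, c("sample_id", bioclim_vars)],
                    n_latent = gcfg$n_latent %||% 2,
                    seed = gcfg$seed %||% seed)
  freqs <- allele_frequencies(g_native, native_meta)
  freqs <- freqs[native_pops, , drop = FALSE]

  coords <- pops[match(native_pops, pops$population_id), c("lon", "lat")]
  qw_native <- q_west$q_west[match(native_pops, q_west$population_id)]
  cond <- cbind(coords, q_west = qw_native)
  rda_fit <- prda(freqs, env_native[bioclim_vars], condition = cond,
                  permutations = gcfg$permutations %||% 199,
                  seed = gcfg$seed %||% seed)
  part <- variance_partition(freqs, env_native[bioclim_vars], coords,
                             data.frame(q_west = qw_native))
  out_rda <- rda_outliers(rda_fit, sd = gcfg$sd_threshold %||% 2.5)
  cand <- combine_candidates(lfmm_candidates(lfmm,
                                             gcfg$q_threshold %||% 0.1),
                             out_rda$locus_id)
  mode <- gcfg$candidate_mode %||% "union"
  cand_loci <- if (identical(mode, "intersection")) cand$shared else
    cand$combined

  enr <- index <- offsets <- mapping <- NULL
  if (length(cand_loci) >= 2) {
    enr <- enriched_rda(freqs, env_native[bioclim_vars], cand_loci,
                        permutations = 0)
    if (!is.null(raster)) {
      index <- adaptive_index(env_scores(enr, 1), raster,
                              std$standardization)
      mapping <- nearest_native_source(fst, pops)
      offsets <- genetic_offset(index, mapping, pops)
      ocfg <- blk("offset")
      offsets$relative_difference <- classify_offsets(
        offsets$offset, mode = ocfg$mode %||% "quantile",
        breaks = ocfg$breaks)
    }
  }

  manifest <- list(
    seed = seed, n_samples = nrow(g$dosages), n_loci = ncol(g$dosages),
    filter = unclass(fcfg), K = K,
    n_candidates = length(cand_loci), candidate_mode = mode,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )

  res <- list(geno = g, meta = meta, env = env, raster = raster,
              truth = truth, diversity = div, models = models,
              ancestry = anc, pca = pca, q_west = q_west, fst = fst,
              beta_fst = beta, tree = tree, mds = mds, lfmm = lfmm,
              prda = rda_fit, partition = part, candidates = cand,
              enriched = enr, index = index, mapping = mapping,
              offsets = offsets, manifest = manifest)

  if (!is.null(config$outdir)) write_pipeline_outputs(res, config$outdir)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_outputs <- function(res, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  wt <- function(x, name) {
    utils::write.table(x, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(res$diversity, "diversity.tsv")
  wt(tidy(res$fst), "pairwise_fst.tsv")
  wt(res$beta_fst, "beta_fst.tsv")
  wt(res$lfmm$stats, "lfmm.tsv")
  wt(as.data.frame(res$partition), "variance_partition.tsv")
  if (!is.null(res$offsets)) wt(res$offsets, "offsets.tsv")
  if (!is.null(res$tree)) ape::write.tree(res$tree,
                                          file.path(outdir, "nj_tree.nwk"))
  write_ancestry(res$ancestry, file.path(outdir, "ancestry"))
  yaml::write_yaml(res$manifest, file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}
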