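# Shared fixtures, generated in code.

# a tiny two-population genotype matrix with known frequencies
toy_two_pops <- function() {
  # pop1: dosages (0, 1); pop2: (2, 2, 1) at locus 1
  # locus 2: pop1 (1, 1); pop2 (0, 1, 0)
  d <- rbind(c(0L, 1L), c(1L, 1L), c(2L, 0L), c(2L, 1L), c(1L, 0L))
  g <- geno_matrix(d, sample_ids = paste0("s", 1:5))
  list(g = g, groups = c("P1", "P1", "P2", "P2", "P2"))
}

# small simulated dataset reused across tests (lazy, cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_native_pops = 12, n_introduced_pops = 6,
                        n_farmed_pops = 3, samples_per_pop = 8,
                        n_loci = 400, n_adaptive_loci = 20, seed = 42)
      cache <<- suppressMessages(simulate_dataset(cfg))
    }
    cache
  }
})

# random genotype matrix with missing entries
random_geno <- function(n = 10, L = 50, miss = 0.1, seed = 1) {
  set.seed(seed)
  p <- stats::runif(L, 0.1, 0.9)
  d <- matrix(stats::rbinom(n * L, 2, rep(p, each = n)), n, L)
  d[stats::runif(n * L) < miss] <- NA_integer_
  geno_matrix(d, sample_ids = paste0("s", seq_len(n)))
}
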