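#' Genotype filter configuration
#'
#' Thresholds for the standard post-calling SNP filters: minimum minor
#' allele count, maximum per-site missingness, maximum per-individual
#' missingness, and thinning to one SNP per RAD locus.
#'
#' @param min_mac Minimum minor allele count; the minor allele is whichever
#'   of REF/ALT is rarer at the site, counted over non-missing alleles.
#' @param max_site_missing Maximum fraction of individuals that may be
#'   missing at a site; 0.2 keeps sites genotyped in at least 80% of
#'   individuals.
#' @param max_indiv_missing Maximum fraction of (site-filtered) loci an
#'   individual may be missing at; 0.5 keeps individuals genotyped in at
#'   least half of the loci.
#' @param one_snp_per_locus Keep only the first SNP (smallest position) of
#'   each `locus_tag`.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_mac = 2, max_site_missing = 0.2,
                          max_indiv_missing = 0.5, one_snp_per_locus = TRUE) {
  stopifnot(min_mac >= 0,
            max_site_missing >= 0, max_site_missing <= 1,
            max_indiv_missing >= 0, max_indiv_missing <= 1)
  structure(list(min_mac = as.integer(min_mac),
                 max_site_missing = max_site_missing,
                 max_indiv_missing = max_indiv_missing,
                 one_snp_per_locus = isTRUE(one_snp_per_locus)),
            class = "filter_config")
}

#' Apply genotype filters
#'
#' Filters are applied in a fixed, documented order, mirroring sequential
#' VCFtools/STACKS calls:
#' 1. sites with minor allele count below `min_mac` are removed;
#' 2. sites with missingness above `max_site_missing` are removed;
#' 3. individuals with missingness (over the remaining sites) above
#'    `max_indiv_missing` are removed;
#' 4. if `one_snp_per_locus`, only the first SNP (lowest position, then
#'    lowest `snp_column`) of each `locus_tag` is kept.
#'
#' Site statistics are computed on the matrix as passed in; they are not
#' re-evaluated after individuals are removed (sequential semantics).
#'
#' @param g A [geno_matrix()].
#' @param cfg A [filter_config()].
#' @return A new, filtered [geno_matrix()]; the input is not modified.
#' @export
apply_filters <- function(g, cfg = filter_config()) {
  stopifnot(inherits(g, "geno_matrix"), inherits(cfg, "filter_config"))
  d <- g$dosages
  if (ncol(d) == 0 || nrow(d) == 0) stop("empty genotype matrix", call. = FALSE)

  # 1. minor allele count
  alt <- colSums(d, na.rm = TRUE)
  tot <- 2L * colSums(!is.na(d))
  mac <- pmin(alt, tot - alt)
  keep_loci <- tot > 0 & mac >= cfg$min_mac

  # 2. site missingness
  site_miss <- colMeans(is.na(d))
  keep_loci <- keep_loci & site_miss <= cfg$max_site_missing

  d2 <- d[, keep_loci, drop = FALSE]
  tab <- g$loci[keep_loci, , drop = FALSE]

  # 3. individual missingness over remaining sites
  if (ncol(d2) > 0) {
    ind_miss <- rowMeans(is.na(d2))
    keep_ind <- ind_miss <= cfg$max_indiv_missing
  } else {
    keep_ind <- rep(TRUE, nrow(d2))
  }
  d2 <- d2[keep_ind, , drop = FALSE]

  # 4. one SNP per locus_tag
  if (cfg$one_snp_per_locus && nrow(tab) > 0) {
    ord <- order(tab$locus_tag, tab$pos,
                 if ("snp_column" %in% names(tab)) tab$snp_column else tab$pos)
    first <- ord[!duplicated(tab$locus_tag[ord])]
    keep_snp <- sort(first)
    d2 <- d2[, keep_snp, drop = FALSE]
    tab <- tab[keep_snp, , drop = FALSE]
  }

  if (ncol(d2) == 0) warning("all loci removed by filters")
  message("apply_filters: ", ncol(g$dosages), " -> ", ncol(d2), " loci; ",
          nrow(g$dosages), " -> ", nrow(d2), " samples")
  geno_matrix(d2, tab, rownames(d2))
}
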