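#' Genotype dosage matrix
#'
#' The central container of the package: a samples-by-loci matrix of ALT
#' allele dosages (0, 1, 2, or `NA` for missing genotypes) together with a
#' per-locus annotation table. Dosage counts assume biallelic SNPs.
#'
#' @param dosages Integer matrix, samples in rows, loci in columns. Values
#'   must be 0, 1, 2 or `NA`. Row names (sample ids) and column names (locus
#'   ids) are taken from `sample_ids` / `loci$locus_id` when present.
#' @param loci A data frame with one row per locus: `locus_id`, `locus_tag`
#'   (the RAD locus a SNP belongs to), `chrom`, `pos` (1-based), `ref`, `alt`.
#'   Missing columns are filled with defaults derived from `locus_id`.
#' @param sample_ids Character vector of unique sample identifiers.
#'
#' @return An object of class `geno_matrix`: a list with elements `dosages`
#'   (integer matrix) and `loci` (tibble).
#' @export
geno_matrix <- function(dosages, loci = NULL, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (is.null(sample_ids)) {
    sample_ids <- paste0("S", seq_len(nrow(dosages)))
  }
  if (is.null(loci)) {
    ids <- colnames(dosages)
    if (is.null(ids)) ids <- paste0("L", seq_len(ncol(dosages)))
    loci <- tibble::tibble(locus_id = ids)
  }
  loci <- tibble::as_tibble(loci)
  if (!"locus_id" %in% names(loci)) {
    stop("`loci` must contain a `locus_id` column", call. = FALSE)
  }
  if (!"locus_tag" %in% names(loci)) loci$locus_tag <- loci$locus_id
  if (!"chrom" %in% names(loci)) loci$chrom <- loci$locus_tag
  if (!"pos" %in% names(loci)) loci$pos <- seq_len(nrow(loci))
  if (!"ref" %in% names(loci)) loci$ref <- "A"
  if (!"alt" %in% names(loci)) loci$alt <- "T"

  if (nrow(loci) != ncol(dosages)) {
    stop("`loci` has ", nrow(loci), " rows but `dosages` has ",
         ncol(dosages), " columns", call. = FALSE)
  }
  if (length(sample_ids) != nrow(dosages)) {
    stop("`sample_ids` length does not match rows of `dosages`", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique", call. = FALSE)
  if (anyDuplicated(loci$locus_id)) stop("locus ids must be unique", call. = FALSE)
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) {
    stop("dosages must be 0, 1, 2 or NA; found ",
         paste(unique(dosages[bad]), collapse = ", "), call. = FALSE)
  }
  dimnames(dosages) <- list(as.character(sample_ids), loci$locus_id)
  structure(list(dosages = dosages, loci = loci), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$dosages), " samples x ", ncol(x$dosages),
      " loci (", format(round(100 * mean(is.na(x$dosages)), 2)),
      "% missing)\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Accessors for `geno_matrix` objects
#'
#' @param g A [geno_matrix()].
#' @return `sample_ids()` the character vector of sample ids; `loci()` the
#'   locus annotation tibble; `dosages()` the integer dosage matrix.
#' @export
sample_ids <- function(g) rownames(g$dosages)

#' @rdname sample_ids
#' @export
loci <- function(g) g$loci

#' @rdname sample_ids
#' @export
dosages <- function(g) g$dosages

#' Subset a genotype matrix by samples and/or loci
#'
#' @param g A [geno_matrix()].
#' @param samples,loci Logical, integer or character index into samples/loci.
#' @return A new `geno_matrix`; the input is never modified.
#' @export
subset_geno <- function(g, samples = NULL, loci = NULL) {
  d <- g$dosages
  tab <- g$loci
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(loci)) {
    if (is.character(loci)) loci <- match(loci, tab$locus_id)
    d <- d[, loci, drop = FALSE]
    tab <- tab[loci, , drop = FALSE]
  }
  geno_matrix(d, tab, rownames(d))
}

#' Sample metadata table
#'
#' Validates a metadata table against a genotype matrix: one row per sample,
#' a population assignment, a status among native / introduced / farmed, and
#' finite geographic coordinates in decimal degrees.
#'
#' @param meta A data frame with columns `sample_id`, `population_id`,
#'   `status`, `lon`, `lat`.
#' @param g Optional [geno_matrix()] to cross-check sample ids against.
#' @return The metadata as a tibble, statuses normalised to lower case.
#' @export
sample_metadata <- function(meta, g = NULL) {
  meta <- tibble::as_tibble(meta)
  need <- c("sample_id", "population_id", "status", "lon", "lat")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("metadata is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  meta$status <- tolower(as.character(meta$status))
  ok <- meta$status %in% c("native", "introduced", "farmed")
  if (!all(ok)) {
    stop("unknown status values: ",
         paste(unique(meta$status[!ok]), collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(meta$lon)) || !all(is.finite(meta$lat))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample ids in metadata", call. = FALSE)
  }
  if (!is.null(g)) {
    missing_meta <- setdiff(sample_ids(g), meta$sample_id)
    if (length(missing_meta)) {
      stop("samples without metadata: ",
           paste(utils::head(missing_meta, 5), collapse = ", "), call. = FALSE)
    }
  }
  meta
}

#' Population table derived from sample metadata
#'
#' One row per population with its status and mean sample coordinates.
#'
#' @param meta A metadata table (see [sample_metadata()]).
#' @return A tibble with `population_id`, `status`, `lon`, `lat`, `n_samples`.
#' @export
population_table <- function(meta) {
  meta |>
    dplyr::group_by(.data$population_id) |>
    dplyr::summarise(
      status = dplyr::first(.data$status),
      lon = mean(.data$lon),
      lat = mean(.data$lat),
      n_samples = dplyr::n(),
      .groups = "drop"
    )
}
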