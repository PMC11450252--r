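#' Genotype-environment (adaptive) index over a raster
#'
#' For every raster pixel, the index is the sum over environmental
#' variables of the variable's score on the chosen constrained-ordination
#' axis times its standardized value at the pixel:
#' `index = sum_j score_j * (env_j - mean_j) / sd_j`. Standardization uses
#' the record from the table the ordination was fit on (typically the
#' native range), so indices are comparable between maps. A pixel whose
#' standardized environment is all zero has index 0; nodata propagates.
#'
#' @param scores Named numeric vector of environmental-variable scores on
#'   the axis (see [env_scores()]).
#' @param raster An [env_raster()] containing a layer for every scored
#'   variable.
#' @param standardization Tibble with `variable`, `mean`, `sd` (see
#'   [standardize_env()]).
#' @return An `adaptive_index` object: the index grid plus the geotransform
#'   and the standardization record used.
#' @export
adaptive_index <- function(scores, raster, standardization) {
  stopifnot(inherits(raster, "env_raster"))
  vars <- names(scores)
  miss <- setdiff(vars, names(raster$grids))
  if (length(miss)) {
    stop("variables missing from raster: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  std <- standardization
  idx <- matrix(0, raster$nrow, raster$ncol)
  for (v in vars) {
    row <- std[std$variable == v, ]
    if (nrow(row) != 1) {
      stop("no standardization record for ", v, call. = FALSE)
    }
    idx <- idx + scores[[v]] * (raster$grids[[v]] - row$mean) / row$sd
  }
  structure(list(index = idx, xmin = raster$xmin, ymin = raster$ymin,
                 cellsize = raster$cellsize, nrow = raster$nrow,
                 ncol = raster$ncol, scores = scores,
                 standardization = std, axis = "RDA1"),
            class = "adaptive_index")
}

#' @export
print.adaptive_index <- function(x, ...) {
  rng <- range(x$index, na.rm = TRUE)
  cat("<adaptive_index> ", x$nrow, " x ", x$ncol, " pixels, range [",
      format(rng[1]), ", ", format(rng[2]), "]\n", sep = "")
  invisible(x)
}

#' Index value at point locations
#'
#' @param idx An [adaptive_index()].
#' @param lon,lat Point coordinates.
#' @return Numeric vector of index values (NA over nodata pixels).
#' @export
index_at <- function(idx, lon, lat) {
  r <- env_raster(list(index = idx$index), xmin = idx$xmin, ymin = idx$ymin,
                  cellsize = idx$cellsize)
  raster_extract(r, lon, lat)$index
}

#' Map each introduced population to its Fst-nearest native source
#'
#' For every introduced population, the native population with the smallest
#' pairwise Fst is taken as the source. Ties break deterministically to the
#' lexicographically first native population id (with a warning).
#'
#' @param fst A [pairwise_fst()] matrix covering all populations.
#' @param meta Sample metadata (or a population table with `population_id`
#'   and `status`).
#' @return A tibble with `population_id` (introduced),
#'   `source_population_id` (native) and `fst`.
#' @export
nearest_native_source <- function(fst, meta) {
  m <- as.matrix(unclass(fst))
  pops <- if ("sample_id" %in% names(meta)) population_table(meta) else
    tibble::as_tibble(meta)
  pops <- pops[match(rownames(m), pops$population_id), ]
  native <- pops$population_id[pops$status == "native"]
  introduced <- pops$population_id[pops$status == "introduced"]
  if (length(native) == 0) stop("no native populations", call. = FALSE)
  native <- sort(native)
  rows <- lapply(introduced, function(ip) {
    v <- m[ip, native]
    if (all(is.na(v))) {
      stop("no defined Fst between ", ip, " and any native population",
           call. = FALSE)
    }
    best <- which(v == min(v, na.rm = TRUE))
    if (length(best) > 1) {
      warning("Fst tie for ", ip, "; choosing ", native[best[1]])
    }
    tibble::tibble(population_id = ip,
                   source_population_id = native[best[1]],
                   fst = unname(v[best[1]]))
  })
  dplyr::bind_rows(rows)
}

#' Genetic offset of introduced populations from their native sources
#'
#' The offset is the absolute difference between the genotype-environment
#' index at the pixel where a population was introduced and the index at
#' the pixel of its Fst-nearest native source. A large offset indicates a
#' mismatch between the environments in which the source genotype occurs
#' natively and the conditions at the introduction site. Population
#' coordinates snap to the pixel containing them; off-raster coordinates
#' are an error.
#'
#' @param idx An [adaptive_index()].
#' @param mapping Output of [nearest_native_source()].
#' @param meta Sample metadata or population table with coordinates.
#' @return An `offset_table` tibble: `population_id`,
#'   `source_population_id`, `index_introduced`, `index_source`,
#'   `offset_signed`, `offset` (absolute).
#' @export
genetic_offset <- function(idx, mapping, meta) {
  pops <- if ("sample_id" %in% names(meta)) population_table(meta) else
    tibble::as_tibble(meta)
  loc <- function(ids) {
    i <- match(ids, pops$population_id)
    if (anyNA(i)) stop("populations missing coordinates: ",
                       paste(ids[is.na(i)], collapse = ", "), call. = FALSE)
    list(lon = pops$lon[i], lat = pops$lat[i])
  }
  li <- loc(mapping$population_id)
  ls <- loc(mapping$source_population_id)
  vi <- index_at(idx, li$lon, li$lat)
  vs <- index_at(idx, ls$lon, ls$lat)
  if (anyNA(vi) || anyNA(vs)) {
    stop("population coordinates fall on nodata pixels", call. = FALSE)
  }
  out <- tibble::tibble(
    population_id = mapping$population_id,
    source_population_id = mapping$source_population_id,
    index_introduced = vi,
    index_source = vs,
    offset_signed = vi - vs,
    offset = abs(vi - vs)
  )
  class(out) <- c("offset_table", class(out))
  out
}

#' Classify offsets into Low / Medium / High
#'
#' In `"quantile"` mode the lower and upper tertiles of the offset vector
#' delimit Low and High, with the rest Medium. In `"fixed"` mode the two
#' user breakpoints are used. Values exactly at a breakpoint fall in the
#' lower class. If all offsets are equal, everything is Low (warning).
#'
#' @param offsets Numeric vector of non-negative offsets.
#' @param mode `"quantile"` or `"fixed"`.
#' @param breaks Length-2 increasing numeric vector for `"fixed"` mode.
#' @return Factor with levels Low, Medium, High.
#' @export
classify_offsets <- function(offsets, mode = c("quantile", "fixed"),
                             breaks = NULL) {
  mode <- match.arg(mode)
  if (mode == "quantile") {
    if (length(offsets) < 3) {
      stop("quantile mode needs at least 3 offsets", call. = FALSE)
    }
    breaks <- unname(stats::quantile(offsets, c(1 / 3, 2 / 3)))
    if (breaks[1] == breaks[2] && diff(range(offsets)) == 0) {
      warning("all offsets equal; classifying everything as Low")
    }
  } else {
    if (is.null(breaks) || length(breaks) != 2 || any(!is.finite(breaks)) ||
        breaks[1] > breaks[2]) {
      stop("fixed mode needs two finite, non-decreasing breaks",
           call. = FALSE)
    }
  }
  lab <- ifelse(offsets <= breaks[1], "Low",
                ifelse(offsets <= breaks[2], "Medium", "High"))
  factor(lab, levels = c("Low", "Medium", "High"))
}

#' Count offsets strictly below a threshold
#'
#' @param offsets Numeric vector.
#' @param threshold Finite threshold.
#' @return Integer count of values strictly less than the threshold.
#' @export
count_below <- function(offsets, threshold) {
  stopifnot(is.finite(threshold) || is.infinite(threshold))
  sum(offsets < threshold)
}

#' Published genetic offsets for 40 introduced tench populations
#'
#' The reference table of genetic offsets (introduced population, its
#' Fst-nearest native source, the genotype-environment index difference and
#' its Low/Medium/High label) for the 40 introduced tench (*Tinca tinca*)
#' populations of the study system this package models. Shipped as a
#' plain-text fixture for context checks and examples.
#'
#' @return A tibble with `introduced_population`, `source_population`,
#'   `offset`, `relative_difference`.
#' @export
tench_offsets <- function() {
  path <- system.file("extdata", "tench_offsets.tsv", package = "genoffset",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}
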