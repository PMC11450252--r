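#' Canonical bioclimatic variable set
#'
#' Default environmental predictors: annual mean temperature, minimum
#' temperature of the coldest month, maximum temperature of the warmest
#' month, temperature seasonality and annual precipitation. This order is
#' also the deterministic tie-break order used by [strongest_variable()].
#' @export
bioclim_vars <- c("AnnMeanTemp", "MinTemp", "MaxTemp", "TempSeason", "AnnPrec")

#' Read a per-population environment table
#'
#' Reads a delimited text file keyed by `population_id` with one named
#' column per environmental variable. Pairwise correlations among the
#' variables are checked; any |r| >= 0.7 produces a collinearity warning
#' (variable pairs that correlated are named).
#'
#' @param path Path to a tab- or comma-delimited file with a header.
#' @param vars Variables expected in the table; default [bioclim_vars].
#' @return A tibble with `population_id` plus one column per variable.
#' @export
read_env_table <- function(path, vars = bioclim_vars) {
  tab <- utils::read.delim(path, sep = "", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"population_id" %in% names(tab)) {
    stop("environment table must have a `population_id` column", call. = FALSE)
  }
  miss <- setdiff(vars, names(tab))
  if (length(miss)) {
    stop("environment table is missing variables: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tab <- tibble::as_tibble(tab[, c("population_id", vars)])
  check_env_collinearity(tab[vars])
  message("read_env_table: ", nrow(tab), " rows, ", length(vars), " variables")
  tab
}

check_env_collinearity <- function(env, limit = 0.7) {
  cm <- stats::cor(as.matrix(env))
  cm[upper.tri(cm, diag = TRUE)] <- 0
  hit <- which(abs(cm) >= limit, arr.ind = TRUE)
  if (nrow(hit)) {
    pairs <- apply(hit, 1, function(i) {
      paste0(rownames(cm)[i[1]], "~", colnames(cm)[i[2]])
    })
    warning("environmental variables with |r| >= ", limit, ": ",
            paste(pairs, collapse = ", "))
  }
  invisible(cm)
}

#' Standardize environmental variables over a reference set of rows
#'
#' Centres and scales each variable using means and standard deviations
#' computed over the reference rows (typically the native range, where the
#' genotype-environment models are fit). The standardization record is kept
#' so the same transform can be applied to rasters and new sites.
#'
#' @param env An environment table (see [read_env_table()]).
#' @param reference Logical or index vector selecting the reference rows;
#'   default all rows.
#' @param vars Variables to standardize.
#' @return A list with `env` (standardized tibble) and `standardization`
#'   (tibble of `variable`, `mean`, `sd`).
#' @export
standardize_env <- function(env, reference = NULL, vars = bioclim_vars) {
  if (is.null(reference)) reference <- rep(TRUE, nrow(env))
  ref <- env[reference, vars, drop = FALSE]
  mu <- vapply(ref, mean, 0)
  sdv <- vapply(ref, stats::sd, 0)
  if (any(sdv == 0)) {
    stop("constant environmental variable(s): ",
         paste(vars[sdv == 0], collapse = ", "), call. = FALSE)
  }
  out <- env
  for (v in vars) out[[v]] <- (env[[v]] - mu[[v]]) / sdv[[v]]
  list(env = out,
       standardization = tibble::tibble(variable = vars, mean = unname(mu),
                                        sd = unname(sdv)))
}

#' Environmental raster stack
#'
#' A named stack of 2-D grids sharing one geotransform. Grids are stored as
#' matrices with row 1 = the northernmost (top) row, matching the ESRI
#' ASCII grid convention; `NA` marks nodata cells.
#'
#' @param grids Named list of numeric matrices with identical dimensions.
#' @param xmin,ymin Coordinates of the lower-left corner of the grid.
#' @param cellsize Cell edge length (square cells).
#' @return An `env_raster` object.
#' @export
env_raster <- function(grids, xmin = 0, ymin = 0, cellsize = 1) {
  stopifnot(is.list(grids), length(grids) > 0, !is.null(names(grids)))
  dims <- lapply(grids, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop("all raster layers must share the same grid shape", call. = FALSE)
  }
  structure(list(grids = grids, xmin = xmin, ymin = ymin,
                 cellsize = cellsize,
                 nrow = nrow(grids[[1]]), ncol = ncol(grids[[1]])),
            class = "env_raster")
}

#' @export
print.env_raster <- function(x, ...) {
  cat("<env_raster> ", x$nrow, " x ", x$ncol, " cells, ",
      length(x$grids), " layer(s): ", paste(names(x$grids), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read a stack of ESRI ASCII grids as an environmental raster
#'
#' Each file is a plain-text `.asc` grid (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `nodata_value` header followed by rows of
#' values, northernmost row first). All grids must share one geotransform.
#'
#' @param paths Named character vector of file paths; names become layer
#'   (variable) names. Unnamed paths use the file base name.
#' @return An [env_raster()].
#' @export
read_raster_stack <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    names(paths) <- tools::file_path_sans_ext(basename(paths))
  }
  layers <- lapply(paths, read_ascii_grid)
  hdr <- lapply(layers, attr, "header")
  ref <- hdr[[1]]
  for (h in hdr[-1]) {
    if (!isTRUE(all.equal(unlist(ref), unlist(h)))) {
      stop("raster layers do not share one geotransform/shape", call. = FALSE)
    }
  }
  grids <- lapply(layers, function(m) { attr(m, "header") <- NULL; m })
  message("read_raster_stack: ", length(grids), " layer(s) of ",
          ref$nrows, " x ", ref$ncols)
  env_raster(grids, xmin = ref$xllcorner, ymin = ref$yllcorner,
             cellsize = ref$cellsize)
}

read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("grid body of ", path, " has ", length(vals), " values; expected ",
         hdr$ncols * hdr$nrows, call. = FALSE)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  attr(m, "header") <- hdr[need]
  m
}

#' Write an environmental raster as ESRI ASCII grids
#'
#' @param r An [env_raster()].
#' @param dir Output directory; one `<layer>.asc` file per layer.
#' @param nodata Value written for `NA` cells.
#' @return Named vector of written paths, invisibly.
#' @export
write_raster_stack <- function(r, dir, nodata = -9999) {
  stopifnot(inherits(r, "env_raster"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(r$grids), function(v) {
    m <- r$grids[[v]]
    m[is.na(m)] <- nodata
    path <- file.path(dir, paste0(v, ".asc"))
    hdr <- c(paste("ncols", r$ncol), paste("nrows", r$nrow),
             paste("xllcorner", r$xmin), paste("yllcorner", r$ymin),
             paste("cellsize", r$cellsize), paste("nodata_value", nodata))
    body <- apply(m, 1, paste, collapse = " ")
    writeLines(c(hdr, body), path)
    path
  }, "")
  invisible(paths)
}

#' Locate the raster cell containing a point
#'
#' @param r An [env_raster()].
#' @param lon,lat Point coordinates (same units as the geotransform).
#' @return A list with `row`, `col` (1-based, row 1 = top) or an error if
#'   the point is off the grid.
#' @export
raster_cell <- function(r, lon, lat) {
  col <- floor((lon - r$xmin) / r$cellsize) + 1L
  row_from_bottom <- floor((lat - r$ymin) / r$cellsize) + 1L
  # points exactly on the top/right edge snap into the last cell
  col <- ifelse(lon == r$xmin + r$ncol * r$cellsize, r$ncol, col)
  row_from_bottom <- ifelse(lat == r$ymin + r$nrow * r$cellsize,
                            r$nrow, row_from_bottom)
  if (any(col < 1 | col > r$ncol | row_from_bottom < 1 |
          row_from_bottom > r$nrow)) {
    stop("point(s) fall outside the raster extent", call. = FALSE)
  }
  list(row = r$nrow - row_from_bottom + 1L, col = col)
}

#' Extract raster values at points
#'
#' @param r An [env_raster()].
#' @param lon,lat Vectors of point coordinates.
#' @param vars Layers to extract; default all.
#' @return A tibble with one row per point and one column per layer;
#'   nodata cells yield `NA`.
#' @export
raster_extract <- function(r, lon, lat, vars = names(r$grids)) {
  cell <- raster_cell(r, lon, lat)
  out <- lapply(vars, function(v) r$grids[[v]][cbind(cell$row, cell$col)])
  names(out) <- vars
  tibble::as_tibble(out)
}
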