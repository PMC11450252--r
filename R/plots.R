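#' Diversity versus ancestry plot
#'
#' Scatter of a diversity metric against the Western-cluster ancestry
#' proportion, coloured by population status, with the fitted
#' status + ancestry-polynomial curve.
#'
#' @param fit A `div_model_fit` (one element of [fit_diversity_models()]).
#' @return A ggplot object.
#' @export
plot_diversity <- function(fit) {
  stopifnot(inherits(fit, "div_model_fit"))
  dat <- fit$data
  grid <- tidyr::expand_grid(
    q_west = seq(0, 1, length.out = 100),
    status = factor(levels(dat$status), levels = levels(dat$status)))
  grid$.fitted <- stats::predict(fit$model, grid, type = "response")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$q_west,
                                    y = .data[[fit$response]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status)) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$.fitted,
                                    group = .data$status),
                       colour = "goldenrod") +
    ggplot2::labs(x = "Ancestry proportion (Western cluster)",
                  y = fit$response) +
    ggplot2::theme_minimal()
}

#' RDA biplot of candidate loci and environmental variables
#'
#' @param x An `rda_scan` (e.g. from [enriched_rda()]).
#' @param axes Which two constrained axes to draw.
#' @param arrow_scale Multiplier applied to the environmental arrows.
#' @return A ggplot object.
#' @export
plot_rda <- function(x, axes = c(1, 2), arrow_scale = NULL) {
  stopifnot(inherits(x, "rda_scan"))
  if (is.null(x$loadings) || ncol(x$loadings) < max(axes)) {
    stop("requested axes not available", call. = FALSE)
  }
  sp <- tibble::as_tibble(x$loadings[, axes, drop = FALSE],
                          rownames = "locus_id")
  names(sp)[2:3] <- c("a1", "a2")
  bp <- tibble::as_tibble(x$env_scores[, axes, drop = FALSE],
                          rownames = "variable")
  names(bp)[2:3] <- c("a1", "a2")
  if (is.null(arrow_scale)) {
    arrow_scale <- max(abs(c(sp$a1, sp$a2))) /
      max(abs(c(bp$a1, bp$a2, 1e-12)))
  }
  lab <- colnames(x$loadings)[axes]
  ggplot2::ggplot(sp, ggplot2::aes(.data$a1, .data$a2)) +
    ggplot2::geom_point(shape = 1, alpha = 0.5, size = 1) +
    ggplot2::geom_segment(
      data = bp,
      ggplot2::aes(x = 0, y = 0, xend = .data$a1 * arrow_scale,
                   yend = .data$a2 * arrow_scale),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "steelblue") +
    ggplot2::geom_text(
      data = bp,
      ggplot2::aes(x = .data$a1 * arrow_scale * 1.08,
                   y = .data$a2 * arrow_scale * 1.08,
                   label = .data$variable),
      colour = "steelblue", size = 3) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
}

#' Map of the genotype-environment index
#'
#' @param idx An [adaptive_index()].
#' @return A ggplot raster map of index values.
#' @export
plot_index <- function(idx) {
  stopifnot(inherits(idx, "adaptive_index"))
  xs <- idx$xmin + (seq_len(idx$ncol) - 0.5) * idx$cellsize
  ys <- idx$ymin + (idx$nrow - seq_len(idx$nrow) + 0.5) * idx$cellsize
  df <- tidyr::expand_grid(row = seq_len(idx$nrow), col = seq_len(idx$ncol))
  df$lon <- xs[df$col]
  df$lat <- ys[df$row]
  df$index <- idx$index[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   fill = .data$index)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "darkred", mid = "white",
                                  high = "darkblue", midpoint = 0,
                                  na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "index") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.rda_scan <- function(object, ...) plot_rda(object, ...)

#' @export
autoplot.adaptive_index <- function(object, ...) plot_index(object)

#' @export
autoplot.div_model_fit <- function(object, ...) plot_diversity(object)
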