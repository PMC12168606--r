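# ggplot2 graphics for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline labs scale_y_log10 geom_raster scale_fill_viridis_c
#'   coord_equal
#' @export
ggplot2::autoplot

#' Plot a structure factor
#'
#' @param sq Tibble (`q`, `s`).
#' @return A ggplot.
#' @export
plot_structure_factor <- function(sq) {
  ggplot(sq, aes(x = .data$q, y = .data$s)) +
    geom_line() +
    geom_hline(yintercept = 1, linetype = "dotted") +
    labs(x = expression(Q ~ (ring(A)^-1)), y = "S(Q)")
}

#' Plot a pair distribution function
#'
#' @param pf Tibble with `r` and `g` (or `t`) columns.
#' @param what Column to draw.
#' @return A ggplot.
#' @export
plot_pair_function <- function(pf, what = c("g", "t")) {
  what <- match.arg(what)
  ggplot(pf, aes(x = .data$r, y = .data[[what]])) +
    geom_line() +
    labs(
      x = expression(r ~ (ring(A))),
      y = if (what == "g") "g(r)" else "T(r)"
    )
}

#' @export
autoplot.cluster_distribution <- function(object, ...) {
  ggplot(object$histogram, aes(x = .data$size, y = .data$count)) +
    geom_col(width = 0.9) +
    scale_y_log10() +
    labs(x = "cluster size (molecules)", y = "count")
}

#' @export
autoplot.calibration_curve <- function(object, ...) {
  grid <- tibble::tibble(
    x_w = seq(min(object$points$x_w), max(object$points$x_w), length.out = 200)
  )
  grid$ratio <- predict(object, grid$x_w)
  ggplot(object$points, aes(x = .data$x_w, y = .data$ratio)) +
    geom_line(data = grid) +
    geom_point() +
    labs(x = "water content (mol%)", y = "peak-height ratio")
}

#' @export
autoplot.composition_estimate <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$iteration, y = .data$x_w)) +
    geom_line() +
    geom_point() +
    labs(x = "iteration", y = "estimated water content (mol%)")
}

#' @export
autoplot.spatial_density_map <- function(object, slice = 0, ...) {
  iz <- which.min(abs(object$axes - slice))
  df <- expand.grid(x = object$axes, y = object$axes)
  df$density <- as.vector(object$density[, , iz])
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$density)) +
    geom_raster() +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(
      x = expression(x ~ (ring(A))), y = expression(y ~ (ring(A))),
      title = sprintf("z = %.1f A slice", object$axes[iz])
    )
}
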