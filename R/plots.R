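# ggplot2 displays for sample batches, textured clouds, and benchmark tables.

#' Plot a sample batch
#'
#' Scatter of the batch in one of its three coordinate systems: the rectangle
#' `(y1, y2)`, the planar domain `(x1, x2)`, or the surface projected on the
#' first two coordinates with the height mapped to color. Uniformity shows as
#' even cover in the y- and surface views.
#'
#' @param object A `sample_batch`.
#' @param space `"y"`, `"x"`, or `"surface"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sample_batch <- function(object, space = c("y", "x", "surface"), ...) {
  space <- match.arg(space)
  if (space == "y")
    p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$y1, y = .data$y2)) +
      ggplot2::geom_point(size = 0.3, alpha = 0.5) +
      ggplot2::labs(x = "y1", y = "y2",
                    title = sprintf("%s sample on the rectangle domain",
                                    object$method[1]))
  else if (space == "x")
    p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x1, y = .data$x2)) +
      ggplot2::geom_point(size = 0.3, alpha = 0.5) +
      ggplot2::labs(x = "x1", y = "x2",
                    title = sprintf("%s sample on the planar domain",
                                    object$method[1]))
  else
    p <- ggplot2::ggplot(object,
                         ggplot2::aes(x = .data$px, y = .data$py,
                                      colour = .data$pz)) +
      ggplot2::geom_point(size = 0.3) +
      ggplot2::coord_fixed() +
      ggplot2::labs(x = "x", y = "y", colour = "z",
                    title = sprintf("%s sample, surface view", object$method[1]))
  p + ggplot2::theme_minimal()
}

#' Plot a textured cloud
#'
#' Projection of the cloud on two world axes with gray values mapped to
#' color; the curved-surface view in which a darker tear region stands out
#' against the bright tendon footprint.
#'
#' @param object A `textured_cloud`.
#' @param axes Which world axes to show (two of `"px"`, `"py"`, `"pz"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.textured_cloud <- function(object, axes = c("px", "py"), ...) {
  stopifnot(length(axes) == 2)
  ggplot2::ggplot(dplyr::filter(object, .data$inside),
                  ggplot2::aes(x = .data[[axes[1]]], y = .data[[axes[2]]],
                               colour = .data$gray)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_colour_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = "textured surface patch")
}

#' Plot a benchmark table
#'
#' Computing time against number of generated points, one line per method,
#' on log-log axes.
#'
#' @param bench A tibble from [benchmark_evaluators()].
#' @return A ggplot object.
#' @export
plot_benchmark <- function(bench) {
  ggplot2::ggplot(bench, ggplot2::aes(x = .data$n, y = .data$seconds,
                                      colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "points generated", y = "median seconds",
                  title = "patch evaluation cost by method")
}
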