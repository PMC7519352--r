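#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a depth-decay curve
#'
#' @param object a `flot_decay`.
#' @param ... unused.
#' @return A ggplot: normalized intensity vs depth with the 1/e line.
#' @export
autoplot.flot_decay <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth_um,
                                       y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = exp(-1), linetype = "dashed") +
    ggplot2::labs(x = "depth (µm)", y = "normalized intensity") +
    ggplot2::theme_minimal()
}

#' Plot a FLOT-vs-MIP comparison
#'
#' Overlays the resampled FLOT and MIP depth-decay curves of the first
#' replicate with the 1/e reference line.
#'
#' @param object a `flot_comparison`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.flot_comparison <- function(object, ...) {
  d <- object$details[[1]]
  df <- tibble::tibble(
    depth_um = rep(d$grid_um, 2),
    intensity = c(d$flot, d$mip),
    modality = rep(c("FLOT", "MIP"), each = length(d$grid_um)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth_um,
                                   y = .data$intensity,
                                   colour = .data$modality)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = exp(-1), linetype = "dashed") +
    ggplot2::labs(x = "depth (µm)", y = "normalized intensity") +
    ggplot2::theme_minimal()
}

#' Image of a reconstruction or projection slice
#'
#' @param image a matrix (e.g. one element of [mip()] output).
#' @param pixel_mm pixel pitch for axis scaling.
#' @return A ggplot raster image.
#' @export
plot_projection <- function(image, pixel_mm = 1) {
  df <- expand.grid(x = seq_len(nrow(image)) * pixel_mm,
                    y = seq_len(ncol(image)) * pixel_mm)
  df$value <- as.numeric(image)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
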