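#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a 1-D spectroscopic summary
#'
#' @param object A `spectro_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectro_summary <- function(object, ...) {
  df <- tibble::as_tibble(object$data)
  xcol <- names(df)[1]
  ycol <- names(df)[2]
  lab <- switch(object$kind,
                emission_spectrum = c("wavelength (nm)", "photons"),
                decay = c("time (ns)", "photons"),
                anisotropy_spectrum = c("wavelength (nm)", "anisotropy"),
                c(xcol, ycol))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xcol]], y = .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = lab[1], y = lab[2],
                  title = object$condition_label) +
    ggplot2::theme_minimal()
}

#' Plot a feature map
#'
#' @param object A `feature_map`.
#' @param ... Unused.
#' @return A ggplot raster of the map (masked pixels blank).
#' @export
autoplot.feature_map <- function(object, ...) {
  df <- tidy.feature_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90",
                                  name = object$units) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$feature_name, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot pooled feature or score histograms
#'
#' @param histograms Tibble from [feature_histograms()] (columns
#'   `condition`, `mid`, `count`).
#' @param pooled Show the pooled overlay (black line).
#' @return A ggplot.
#' @export
plot_histograms <- function(histograms, pooled = TRUE) {
  per <- dplyr::filter(histograms, .data$condition != "pooled")
  p <- ggplot2::ggplot(per, ggplot2::aes(x = .data$mid, y = .data$count,
                                         colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "feature value", y = "pixels") +
    ggplot2::theme_minimal()
  if (pooled && any(histograms$condition == "pooled")) {
    p <- p + ggplot2::geom_line(
      data = dplyr::filter(histograms, .data$condition == "pooled"),
      colour = "black", linewidth = 0.8)
  }
  p
}

#' Plot a dimensionality sweep
#'
#' Worst-pair and mean separability per feature space, in sweep order.
#'
#' @param sweep Tibble from [dimensionality_sweep()].
#' @return A ggplot.
#' @export
plot_sweep <- function(sweep) {
  df <- tidyr::pivot_longer(sweep, c("worst_S", "mean_S"),
                            names_to = "statistic", values_to = "S")
  df$space <- factor(df$space, levels = unique(sweep$space))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$space, y = .data$S,
                                   group = .data$statistic,
                                   colour = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "feature space", y = "separability index S") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
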