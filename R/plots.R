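# ggplot2 visualizations for the main result types.

#' @export
autoplot.visual_semantic_map <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$semantic_pc, y = .data$visual_pc,
                                 fill = .data$coefficient)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Semantic PC", y = "Visual PC", fill = "Coefficient",
                  title = "Visual-semantic matrix") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.coef_test <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$semantic_pc, y = .data$visual_pc,
                                 fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = ~ dplyr::filter(.x, .data$significant),
                       fill = NA, color = "black", linewidth = 0.4) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Semantic PC", y = "Visual PC", fill = "Z",
                  title = sprintf("Coefficient Z scores (critical |Z| = %.2f)",
                                  object$critical)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.synthesis_result <- function(object, ...) {
  lab <- if (object$objective == "mse") "Mean squared error" else "Caricature objective"
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::labs(x = "Iteration", y = lab, title = "Optimization trace") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rdm <- function(object, ...) {
  m <- object$distances
  df <- tidyr::expand_grid(a = object$labels, b = object$labels)
  df$distance <- as.numeric(t(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$a,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Distance",
                  title = "Representational dissimilarity matrix") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot a rendered image array
#'
#' @param image Array `h x w x 3` in `[0, 1]`.
#' @return A ggplot object.
#' @export
plot_image <- function(image) {
  d <- dim(image)
  df <- tidyr::expand_grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$fill <- grDevices::rgb(pmin(pmax(image[, , 1], 0), 1)[cbind(df$row, df$col)],
                            pmin(pmax(image[, , 2], 0), 1)[cbind(df$row, df$col)],
                            pmin(pmax(image[, , 3], 0), 1)[cbind(df$row, df$col)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot a 2-D concept embedding
#'
#' @param layout The tibble returned by [embed_2d()].
#' @return A ggplot object.
#' @export
plot_embedding_2d <- function(layout) {
  ggplot2::ggplot(layout, ggplot2::aes(x = .data$x, y = .data$y,
                                       label = .data$label)) +
    ggplot2::geom_point(color = "#2c7fb8") +
    ggplot2::geom_text(vjust = -0.7, size = 3) +
    ggplot2::labs(x = NULL, y = NULL, title = "Concept map (t-SNE)") +
    ggplot2::theme_minimal()
}
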