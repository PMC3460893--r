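#' Plot a vector layer
#'
#' Draws every ring as a filled polygon (holes render via the even-odd
#' subpath rule of `ggplot2::geom_polygon`'s `subgroup` aesthetic).
#'
#' @param object a `vector_layer`.
#' @param fill fill colour.
#' @param ... passed to [ggplot2::geom_polygon()].
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.vector_layer <- function(object, fill = "grey70", ...) {
  df <- .layer_fortify(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   group = .data$ring_id,
                                   subgroup = .data$ring)) +
    ggplot2::geom_polygon(fill = fill, colour = "grey30", linewidth = 0.2, ...) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
}

.layer_fortify <- function(layer) {
  rows <- lapply(seq_len(nrow(layer)), function(i) {
    g <- layer$geometry[[i]]
    dplyr::bind_rows(lapply(seq_along(g), function(j) {
      tibble(id = layer$id[i], ring = j,
             ring_id = paste0(layer$id[i], ".", j),
             x = g[[j]]$x, y = g[[j]]$y)
    }))
  })
  dplyr::bind_rows(rows)
}

#' Map a synthetic landscape
#'
#' States, priority patches and parcels on one panel.
#'
#' @param landscape result of [simulate_landscape()].
#' @param max_parcels subsample cap so dense landscapes stay drawable.
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape, max_parcels = 2000) {
  lands <- landscape$lands
  if (nrow(lands) > max_parcels) {
    lands <- .relayer(lands[seq_len(max_parcels), , drop = FALSE], lands)
  }
  p <- ggplot2::ggplot(mapping = ggplot2::aes(.data$x, .data$y, group = .data$ring_id)) +
    ggplot2::geom_polygon(data = .layer_fortify(landscape$states),
                          fill = "white", colour = "black", linewidth = 0.4) +
    ggplot2::geom_polygon(data = .layer_fortify(landscape$priorities),
                          fill = "darkseagreen2", colour = "darkseagreen4", linewidth = 0.2)
  if (nrow(lands) > 0) {
    p <- p + ggplot2::geom_polygon(data = .layer_fortify(lands),
                                   fill = "orange3", colour = NA, alpha = 0.8)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
}

#' Plot an alignment report
#'
#' Science influence score by stratum, with the chance level at zero.
#'
#' @param object an `alignment_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.alignment_report <- function(object, ...) {
  tb <- object$by_stratum
  tb <- tb[!is.na(tb$score), , drop = FALSE]
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$stratum, y = 100 * .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "science influence score (%)") +
    ggplot2::theme_minimal()
}
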