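#' Plot an axial slice of a volume map
#'
#' @param object A `volume_map`.
#' @param z mm coordinate of the axial slice (default: the grid midplane).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot volume_map
#' @export
autoplot.volume_map <- function(object, z = NULL, ...) {
  df <- tidy(object)
  if (is.null(z)) z <- stats::median(unique(df$z))
  zs <- unique(df$z)
  z_near <- zs[which.min(abs(zs - z))]
  ggplot2::ggplot(dplyr::filter(df, .data$z == z_near),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("axial slice z = %g mm", z_near),
                  x = "x (mm)", y = "y (mm)", fill = "value") +
    ggplot2::theme_minimal()
}

#' Plot a 1 - r distance matrix
#'
#' @param object An `ale_dist` matrix.
#' @param order Optional permutation (e.g. from [reorder_matrix()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ale_dist
#' @export
autoplot.ale_dist <- function(object, order = NULL, ...) {
  lab <- rownames(object)
  if (!is.null(order)) lab <- lab[order]
  df <- tidyr::expand_grid(network_a = lab, network_b = lab) %>%
    mutate(distance = object[cbind(.data$network_a, .data$network_b)],
           network_a = factor(.data$network_a, levels = lab),
           network_b = factor(.data$network_b, levels = rev(lab)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$network_a,
                                   y = .data$network_b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "1 - r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a classical MDS embedding of the networks
#'
#' @param object An `ale_mds` embedding.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ale_mds
#' @export
autoplot.ale_mds <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   label = .data$network)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "dimension 1", y = "dimension 2",
                  title = sprintf("classical MDS (stress-1 = %.3g)",
                                  object$stress)) +
    ggplot2::theme_minimal()
}

#' Bar plot of a reference-similarity profile
#'
#' @param profile A tibble from [centrality_profile()].
#' @return A ggplot object.
#' @export
plot_centrality <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = stats::reorder(.data$network,
                                                  .data$similarity),
                               y = .data$similarity)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "spatial similarity (1 - distance)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
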