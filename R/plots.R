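#' Plot a B-scan with optional traced boundaries
#'
#' @param object A [bscan].
#' @param boundaries Optional `layer_boundaries` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bscan <- function(object, boundaries = NULL, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$pixels)),
                           col = seq_len(ncol(object$pixels)))
  df$intensity <- as.vector(object$pixels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "A-scan", y = "depth (px)",
                  title = sprintf("slice %d", object$slice_index)) +
    ggplot2::theme_minimal()
  if (!is.null(boundaries)) {
    p <- p + ggplot2::geom_line(
      data = dplyr::filter(as_tibble(boundaries), !is.na(.data$row_px)),
      ggplot2::aes(x = .data$column, y = .data$row_px,
                   colour = .data$boundary),
      linewidth = 0.3, inherit.aes = FALSE)
  }
  p
}

#' Scatter plot of inter-eye asymmetries
#'
#' The GCL/IPL asymmetry against the INL asymmetry, one point per
#' subject, cyst-positive subjects marked by shape.
#'
#' @param object An `asymmetry_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.asymmetry_result <- function(object, ...) {
  r <- object$records
  lab <- if (!is.null(object$correlation)) {
    sprintf("r = %.2f, p = %.3g", object$correlation$r, object$correlation$p)
  } else "correlation undefined"
  ggplot2::ggplot(r, ggplot2::aes(x = .data$d_gclipl_um, y = .data$d_inl_um,
                                  shape = .data$cyst)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 18, `TRUE` = 17),
                                name = "microcysts") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40",
                         ggplot2::aes(shape = NULL)) +
    ggplot2::labs(x = "Δ GCL/IPL (ON - fellow, µm)",
                  y = "Δ INL (ON - fellow, µm)",
                  subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Topographic map of group deviations
#'
#' Polar tile map of the per-point deviation (thinning positive for
#' RNFL/GCL-IPL, thickening positive for INL), one facet per layer.
#'
#' @param object A `deviation_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.deviation_map <- function(object, ...) {
  m <- dplyr::mutate(object$map, angle = (.data$line - 1) * 30)
  ggplot2::ggplot(m, ggplot2::aes(x = factor(.data$angle),
                                  y = factor(.data$eccentricity_um),
                                  fill = .data$deviation_um)) +
    ggplot2::geom_tile() +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::facet_wrap(~ .data$layer) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", name = "µm") +
    ggplot2::labs(x = "radial line angle (deg, temporal = 0)",
                  y = "eccentricity (µm)") +
    ggplot2::theme_minimal()
}

#' Thickness grid plot
#'
#' @param object A `thickness_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.thickness_grid <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$line, y = .data$thickness_um,
                               colour = factor(.data$eccentricity_um))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~ .data$layer, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = 1:12) +
    ggplot2::labs(x = "radial line", y = "thickness (µm)",
                  colour = "eccentricity (µm)") +
    ggplot2::theme_minimal()
}
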