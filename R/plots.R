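#' Plot a field solution
#'
#' Heat map of the order-parameter magnitude with a subsampled quiver of
#' the in-plane field over the meridional slice.
#'
#' @param object A `field_solution`.
#' @param arrows Approximate number of arrows.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot field_solution
#' @export
autoplot.field_solution <- function(object, arrows = 250, ...) {
  df <- tidy(object)
  sub <- df[seq(1, nrow(df), length.out = min(arrows, nrow(df))), ]
  sc <- 0.06 * max(sqrt(df$x^2 + df$z^2)) / max(df$magnitude, 1e-12)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$magnitude), size = 0.8) +
    ggplot2::geom_segment(
      data = sub,
      ggplot2::aes(xend = .data$x + sc * .data$px,
                   yend = .data$z + sc * .data$pz),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.2, "mm")),
      linewidth = 0.25) +
    ggplot2::scale_colour_viridis_c(name = "|p|") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x / R0", y = "z / R0") +
    ggplot2::theme_minimal()
}

#' Plot a nematic map
#'
#' Heat map of the nematic strength with director line segments and the
#' rotationally averaged boundary.
#'
#' @param object A `nematic_map`.
#' @param every Director segment subsampling stride.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nematic_map
#' @export
autoplot.nematic_map <- function(object, every = 3, ...) {
  df <- tidy(object)
  occ <- df[!is.na(df$Vx) & df$n_samples > 0, ]
  occ <- occ[seq(1, nrow(occ), by = every), ]
  len <- 0.45 * diff(object$x[1:2]) * every
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$Lambda)) +
    ggplot2::geom_segment(
      data = occ,
      ggplot2::aes(x = .data$x - len * .data$Vx, y = .data$z - len * .data$Vz,
                   xend = .data$x + len * .data$Vx,
                   yend = .data$z + len * .data$Vz),
      colour = "white", linewidth = 0.3) +
    ggplot2::geom_path(data = object$boundary,
                       ggplot2::aes(x = .data$x, y = .data$z),
                       colour = "red", linewidth = 0.4) +
    ggplot2::scale_fill_viridis_c(name = "Lambda") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (normalized)", y = "z (normalized)") +
    ggplot2::theme_minimal()
}

#' Plot a material-length cost surface
#'
#' Log-scaled tile map of the fit cost over \eqn{(\xi/R_0, \lambda/R_0)}
#' with the best fit marked.
#'
#' @param object A `fit_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fit_result
#' @export
autoplot.fit_result <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(x = .data$xi_rel, y = .data$lambda_rel)) +
    ggplot2::geom_tile(ggplot2::aes(fill = log10(.data$C))) +
    ggplot2::geom_point(data = object$best, colour = "red", size = 2,
                        shape = 8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "log10 C") +
    ggplot2::labs(x = "xi / R0", y = "lambda / R0") +
    ggplot2::theme_minimal()
}

#' Plot a phase diagram tibble
#'
#' Global order as a tile map over the parameter grid with the
#' defect-containing region outlined.
#'
#' @param pd Output of [phase_diagram()].
#' @return A ggplot object.
#' @export
plot_phase_diagram <- function(pd) {
  ggplot2::ggplot(pd, ggplot2::aes(x = .data$xi_rel, y = .data$lambda_rel)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$P)) +
    ggplot2::geom_point(data = pd[pd$n_defects > 0, ], colour = "white",
                        size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "P") +
    ggplot2::labs(x = "xi / R0", y = "lambda / R0",
                  subtitle = "white dots: defect-containing minima") +
    ggplot2::theme_minimal()
}

#' Plot boundary-angle distributions
#'
#' Violin-style summary of cell-boundary angles split by cap side, the
#' per-cap distribution the stage comparisons use.
#'
#' @param cells Tibble from [quantify_cells()], with a `cap` column
#'   (e.g. from [split_caps()]).
#' @return A ggplot object.
#' @export
plot_boundary_angles <- function(cells) {
  df <- cells[cells$touches_boundary & !is.na(cells$boundary_angle_deg), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cap, y = .data$boundary_angle_deg)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.08, size = 0.8, alpha = 0.6) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, colour = "red", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "cell-boundary angle (deg)") +
    ggplot2::theme_minimal()
}

#' Split boundary cells by cap side
#'
#' Labels each boundary-touching cell `"alpha"` or `"beta"` according to
#' which side of the interface plane its centroid lies on (the plane from
#' [determine_axis()]); interior cells get `NA`.
#'
#' @param cells Tibble from [quantify_cells()].
#' @param frame An `axis_frame`.
#' @return `cells` with an added `cap` column.
#' @export
split_caps <- function(cells, frame) {
  cen <- as.matrix(cells[, c("centroid_x", "centroid_y", "centroid_z")])
  h <- (cen - matrix(frame$x0, nrow(cen), 3, byrow = TRUE)) %*% frame$axis
  cells$cap <- ifelse(!cells$touches_boundary, NA_character_,
                      ifelse(h[, 1] > frame$interface_height, "alpha", "beta"))
  cells
}
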