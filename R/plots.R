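#' Plot a radial dose kernel
#'
#' Log-log excess dose versus radial distance.
#'
#' @param object A `radial_dose_kernel`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot radial_dose_kernel
#' @export
autoplot.radial_dose_kernel <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$r_mid_nm, y = .data$dose_gy_per_gy)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "radial distance (nm)",
      y = "excess dose (Gy per GNP per Gy prescribed)",
      title = sprintf("%g nm GNP radial dose kernel", object$diameter_nm)
    )
}

#' Plot a GNP placement
#'
#' x-y projection of the GNP coordinates with the cell and nucleus
#' outlines.
#'
#' @param object A [sample_gnp_positions()] result.
#' @param max_points Subsample cap for plotting. Default 20000.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gnp_placement
#' @export
autoplot.gnp_placement <- function(object, max_points = 20000, ...) {
  geom <- attr(object, "geometry") %||% cell_geometry()
  pts <- as_tibble(object)
  if (nrow(pts) > max_points) {
    pts <- pts[seq(1, nrow(pts), length.out = max_points), ]
  }
  th <- seq(0, 2 * pi, length.out = 361)
  cell <- tibble(x = geom$semi_axis_a_um * cos(th), y = geom$semi_axis_b_um * sin(th))
  nuc <- tibble(x = geom$nucleus_radius_um * cos(th), y = geom$nucleus_radius_um * sin(th))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x_um, y = .data$y_um)) +
    ggplot2::geom_point(size = 0.2, alpha = 0.3) +
    ggplot2::geom_path(data = cell, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = nuc, ggplot2::aes(x = .data$x, y = .data$y), linetype = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (um)", y = "y (um)",
      title = sprintf("GNP placement: %s", attr(object, "scenario") %||% "")
    )
}

#' Plot a GNP-LEM study
#'
#' Scenario-averaged percent survival-fraction reduction with per-seed
#' points.
#'
#' @param object A [run_lem_study()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gnp_lem_study
#' @export
autoplot.gnp_lem_study <- function(object, ...) {
  per <- tidy(object)
  ggplot2::ggplot(per, ggplot2::aes(x = .data$scenario, y = .data$mean_reduction_pct)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_point(
      data = as_tibble(object),
      ggplot2::aes(x = .data$scenario, y = .data$reduction_pct)
    ) +
    ggplot2::labs(
      x = NULL, y = "SF reduction (%)",
      title = sprintf("GNP-LEM predicted radiosensitization (%g nm)", per$diameter_nm[1])
    )
}

#' Plot tumor control probability over fraction number
#'
#' @param object A [tcp_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tcp_curve
#' @export
autoplot.tcp_curve <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$n_treatments, y = .data$tcp, colour = .data$schedule)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "number of treatments", y = "tumor control probability",
      colour = "per-treatment SF"
    )
}
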