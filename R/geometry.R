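#' Elliptical cell model with a central spherical nucleus
#'
#' The cell is an axis-aligned ellipsoid centred at the origin; the nucleus
#' is a sphere at the centre. Defaults reproduce a flattened epithelial
#' breast-cancer cell: 15.5 um by 11.5 um elliptical diameters with an 8 um
#' diameter nucleus. The third semi-axis is not constrained by 2D
#' microscopy; it defaults to the minor semi-axis.
#'
#' @param semi_axis_a_um,semi_axis_b_um,semi_axis_c_um Cell semi-axes (um).
#' @param nucleus_radius_um Nucleus radius (um); the nucleus sphere must lie
#'   strictly inside the cell ellipsoid.
#' @return A list of class `"cell_geometry"`.
#' @examples
#' cell_geometry()
#' @export
cell_geometry <- function(semi_axis_a_um = 7.75,
                          semi_axis_b_um = 5.75,
                          semi_axis_c_um = 5.75,
                          nucleus_radius_um = 4) {
  axes <- c(semi_axis_a_um, semi_axis_b_um, semi_axis_c_um)
  if (any(axes <= 0) || nucleus_radius_um <= 0) {
    abort("All semi-axes and the nucleus radius must be positive.")
  }
  if (nucleus_radius_um >= min(axes)) {
    abort("The nucleus sphere must lie strictly inside the cell ellipsoid.")
  }
  structure(
    list(
      semi_axis_a_um = semi_axis_a_um,
      semi_axis_b_um = semi_axis_b_um,
      semi_axis_c_um = semi_axis_c_um,
      nucleus_radius_um = nucleus_radius_um
    ),
    class = "cell_geometry"
  )
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "<cell_geometry> ellipsoid %g x %g x %g um semi-axes, nucleus r = %g um\n",
    x$semi_axis_a_um, x$semi_axis_b_um, x$semi_axis_c_um, x$nucleus_radius_um
  ))
  invisible(x)
}

#' Endosomal vesicle specification
#'
#' @param diameter_nm Vesicle diameter in nanometres. Default 500.
#' @param occupancy GNPs per vesicle (>= 1). Default 100.
#' @return A list of class `"vesicle_spec"`.
#' @export
vesicle_spec <- function(diameter_nm = 500, occupancy = 100) {
  if (diameter_nm <= 0) abort("`diameter_nm` must be positive.")
  if (occupancy < 1) abort("`occupancy` must be at least 1.")
  structure(
    list(diameter_nm = diameter_nm, occupancy = as.integer(occupancy)),
    class = "vesicle_spec"
  )
}

#' Signed distance from a point to the nucleus surface
#'
#' Negative inside the nucleus, zero on its surface, positive in the
#' cytoplasm. Exact for the spherical nucleus.
#'
#' @param x,y,z Point coordinates in micrometres; vectorised.
#' @param geometry A [cell_geometry()].
#' @return Signed distances in micrometres.
#' @examples
#' distance_to_nucleus_surface(0, 0, 0)   # -4
#' distance_to_nucleus_surface(0, 5, 0)   # +1
#' @export
distance_to_nucleus_surface <- function(x, y, z, geometry = cell_geometry()) {
  sqrt(x^2 + y^2 + z^2) - geometry$nucleus_radius_um
}

# Inside-ellipsoid predicate (boundary counts as inside).
inside_cell <- function(x, y, z, geometry) {
  (x / geometry$semi_axis_a_um)^2 +
    (y / geometry$semi_axis_b_um)^2 +
    (z / geometry$semi_axis_c_um)^2 <= 1
}

#' Number of vesicles needed for a GNP load
#'
#' Vesicles are filled to `occupancy`; the last vesicle holds the
#' remainder, so the count is the ceiling of `n_gnp / occupancy`.
#'
#' @param n_gnp Total internalized GNP count (>= 0).
#' @param occupancy GNPs per vesicle (>= 1).
#' @return Integer vesicle count.
#' @examples
#' pack_vesicles(367000, 100)  # 3670
#' @export
pack_vesicles <- function(n_gnp, occupancy = 100) {
  if (any(n_gnp < 0)) abort("`n_gnp` must be non-negative.")
  if (any(occupancy < 1)) abort("`occupancy` must be at least 1.")
  as.integer(ceiling(n_gnp / occupancy))
}
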