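#' Sample intracellular GNP positions under a distribution scenario
#'
#' Draws `n_gnp` GNP centre coordinates inside the cytoplasm (inside the cell
#' ellipsoid, outside the nucleus sphere — internalized GNPs do not enter the
#' nucleus) under one of three scenarios:
#'
#' * `"uniform_cytoplasm"` — rejection sampling, uniform over the cytoplasm.
#' * `"perinuclear"` — uniform cytoplasm proposals accepted with probability
#'   `exp(-d / decay_length_um)` where `d` is the distance to the nucleus
#'   surface, concentrating GNPs near the nuclear envelope.
#' * `"vesicle"` — `ceiling(n_gnp / occupancy)` non-overlapping vesicles are
#'   dart-thrown uniformly in the cytoplasm (whole vesicle inside it), then
#'   each vesicle is filled with `occupancy` GNPs uniform in its sphere; the
#'   last vesicle holds the remainder.
#'
#' The same `seed` gives bit-identical output.
#'
#' @param n_gnp Number of GNPs to place (>= 0).
#' @param scenario One of `"uniform_cytoplasm"`, `"perinuclear"`, `"vesicle"`.
#' @param geometry A [cell_geometry()].
#' @param gnp_diameter_nm GNP core diameter (metadata carried to the dose
#'   step). Default 10.
#' @param decay_length_um Exponential decay length of the perinuclear
#'   scenario (um). Default 1.
#' @param vesicle A [vesicle_spec()]; used only by the vesicle scenario.
#' @param seed Optional integer seed.
#' @param max_consecutive_fail Retry budget for vesicle dart-throwing.
#' @return A tibble of class `"gnp_placement"` with columns `x_um`, `y_um`,
#'   `z_um` (and `vesicle_id` for the vesicle scenario) plus attributes
#'   `scenario`, `gnp_diameter_nm`, `seed`, `geometry`.
#' @examples
#' p <- sample_gnp_positions(1000, "perinuclear", seed = 1)
#' summary(distance_to_nucleus_surface(p$x_um, p$y_um, p$z_um))
#' @export
sample_gnp_positions <- function(n_gnp,
                                 scenario = c("uniform_cytoplasm", "perinuclear", "vesicle"),
                                 geometry = cell_geometry(),
                                 gnp_diameter_nm = 10,
                                 decay_length_um = 1,
                                 vesicle = vesicle_spec(),
                                 seed = NULL,
                                 max_consecutive_fail = 100000) {
  scenario <- match.arg(scenario)
  if (n_gnp < 0) abort("`n_gnp` must be non-negative.")
  if (decay_length_um <= 0) abort("`decay_length_um` must be positive.")
  n_gnp <- as.integer(n_gnp)

  coords <- with_optional_seed(seed, {
    switch(scenario,
      uniform_cytoplasm = sample_cytoplasm_uniform(n_gnp, geometry),
      perinuclear = sample_perinuclear(n_gnp, geometry, decay_length_um),
      vesicle = sample_in_vesicles(n_gnp, geometry, vesicle, max_consecutive_fail)
    )
  })

  structure(
    coords,
    scenario = scenario,
    gnp_diameter_nm = gnp_diameter_nm,
    seed = seed,
    geometry = geometry,
    class = c("gnp_placement", class(coords))
  )
}

# Uniform points in the unit ball, scaled to the ellipsoid axes (a linear
# map preserves uniformity), nucleus interior rejected.
sample_cytoplasm_uniform <- function(n, geometry, weight_fun = NULL) {
  out_x <- numeric(0); out_y <- numeric(0); out_z <- numeric(0)
  need <- n
  while (need > 0L) {
    m <- max(2L * need, 1000L)
    u <- matrix(rnorm(3 * m), ncol = 3)
    nrm <- sqrt(rowSums(u^2))
    r <- runif(m)^(1 / 3)
    x <- u[, 1] / nrm * r * geometry$semi_axis_a_um
    y <- u[, 2] / nrm * r * geometry$semi_axis_b_um
    z <- u[, 3] / nrm * r * geometry$semi_axis_c_um
    keep <- sqrt(x^2 + y^2 + z^2) >= geometry$nucleus_radius_um
    if (!is.null(weight_fun)) {
      w <- weight_fun(x, y, z)
      keep <- keep & (runif(m) < w)
    }
    x <- x[keep]; y <- y[keep]; z <- z[keep]
    take <- min(length(x), need)
    if (take > 0L) {
      out_x <- c(out_x, x[seq_len(take)])
      out_y <- c(out_y, y[seq_len(take)])
      out_z <- c(out_z, z[seq_len(take)])
      need <- need - take
    }
  }
  tibble(x_um = out_x, y_um = out_y, z_um = out_z)
}

sample_perinuclear <- function(n, geometry, decay_length_um) {
  sample_cytoplasm_uniform(n, geometry, weight_fun = function(x, y, z) {
    d <- distance_to_nucleus_surface(x, y, z, geometry)
    exp(-pmax(d, 0) / decay_length_um)
  })
}

sample_in_vesicles <- function(n, geometry, vesicle, max_consecutive_fail) {
  if (n == 0L) {
    return(tibble(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                  vesicle_id = integer(0)))
  }
  n_ves <- pack_vesicles(n, vesicle$occupancy)
  r_ves <- vesicle$diameter_nm / 2 / 1000 # um
  centers <- .rsa_pack_centers_cpp(
    n_ves, r_ves,
    geometry$semi_axis_a_um, geometry$semi_axis_b_um, geometry$semi_axis_c_um,
    geometry$nucleus_radius_um, as.integer(max_consecutive_fail)
  )
  per_ves <- rep(vesicle$occupancy, n_ves)
  per_ves[n_ves] <- n - vesicle$occupancy * (n_ves - 1L)
  vesicle_id <- rep.int(seq_len(n_ves), per_ves)
  # uniform in each vesicle sphere
  u <- matrix(rnorm(3 * n), ncol = 3)
  nrm <- sqrt(rowSums(u^2))
  r <- r_ves * runif(n)^(1 / 3)
  tibble(
    x_um = centers[vesicle_id, 1] + u[, 1] / nrm * r,
    y_um = centers[vesicle_id, 2] + u[, 2] / nrm * r,
    z_um = centers[vesicle_id, 3] + u[, 3] / nrm * r,
    vesicle_id = vesicle_id
  )
}

#' @export
print.gnp_placement <- function(x, ...) {
  cat(sprintf(
    "<gnp_placement> %d GNPs (%g nm), scenario '%s'\n",
    nrow(x), attr(x, "gnp_diameter_nm"), attr(x, "scenario")
  ))
  NextMethod()
}
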