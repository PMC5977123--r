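#' Radial excess-dose kernels around a single gold nanoparticle
#'
#' A `radial_dose_kernel` stores the excess dose deposited in water at radial
#' distance r from one irradiated GNP, per 1 Gy of prescribed macroscopic
#' dose, as a piecewise-constant function on radial bins. Kernels of this
#' kind are normally produced by track-structure Monte Carlo codes; this
#' package generates a calibrated power-law stand-in (see
#' [make_power_law_kernel()]) and can read externally computed tables via
#' [read_kernel_table()].
#'
#' @name radial_dose_kernel
NULL

#' Kernel calibration parameters
#'
#' The power-law kernel is pinned to a total-energy target: the energy
#' deposited in water per GNP per 1 Gy prescribed equals
#' `eta * (gold mass of the GNP) * 1 Gy`. `eta` is the dimensionless excess
#' absorption of the gold sphere relative to the water it displaces,
#' spectrum-averaged over the beam at depth.
#'
#' @param eta Dimensionless excess-absorption factor (>= 0). Default 0.5.
#' @param exponent Power-law falloff exponent (> 0); dose ~ r^-exponent.
#'   Default 2.
#' @param r_max_um Kernel range in micrometres (dose is exactly zero
#'   beyond it). Default 5.
#' @return A list of class `"kernel_calibration"`.
#' @examples
#' kernel_calibration(eta = 0.5)
#' @export
kernel_calibration <- function(eta = 0.5, exponent = 2, r_max_um = 5) {
  if (eta < 0) abort("`eta` must be >= 0.")
  if (exponent <= 0) abort("`exponent` must be > 0.")
  if (r_max_um <= 0) abort("`r_max_um` must be > 0.")
  structure(
    list(
      eta = eta, exponent = exponent, r_max_um = r_max_um,
      gold_density = GOLD_DENSITY_G_CM3, water_density = WATER_DENSITY_G_CM3
    ),
    class = "kernel_calibration"
  )
}

new_radial_dose_kernel <- function(diameter_nm, bin_edges_nm, dose_gy_per_gy,
                                   calibration) {
  k <- structure(
    list(
      diameter_nm = diameter_nm,
      bin_edges_nm = bin_edges_nm,
      dose_gy_per_gy = dose_gy_per_gy,
      calibration = calibration
    ),
    class = "radial_dose_kernel"
  )
  validate_kernel(k)
}

validate_kernel <- function(k) {
  edges <- k$bin_edges_nm
  dose <- k$dose_gy_per_gy
  if (length(edges) != length(dose) + 1L) {
    abort("Kernel must have one more bin edge than dose values.")
  }
  if (any(diff(edges) <= 0)) abort("Kernel bin edges must be strictly increasing.")
  if (any(dose < 0)) abort("Kernel doses must be non-negative.")
  if (edges[1] < k$diameter_nm / 2 - 1e-9) {
    abort("First bin edge must be at or beyond the GNP surface.")
  }
  k
}

#' Generate a calibrated power-law radial dose kernel
#'
#' Dose falls off as `r^-exponent`, evaluated at bin midpoints from the GNP
#' surface to `r_max_um`, then rescaled so that the shell-integrated energy
#' (dose x shell mass of water, summed over bins) equals
#' `eta * gold mass * 1 Gy` in joules.
#'
#' @param diameter_nm GNP core diameter in nanometres (> 0).
#' @param calibration A [kernel_calibration()].
#' @param n_bins Number of radial bins (>= 10). Default 200.
#' @return A `radial_dose_kernel`.
#' @examples
#' k <- make_power_law_kernel(10)
#' kernel_total_energy_j(k) / (0.5 * gnp_gold_mass(10, "kg"))  # ~1
#' @export
make_power_law_kernel <- function(diameter_nm,
                                  calibration = kernel_calibration(),
                                  n_bins = 200) {
  if (diameter_nm <= 0) abort("`diameter_nm` must be positive.")
  if (n_bins < 10) abort("`n_bins` must be at least 10.")
  r0 <- diameter_nm / 2
  r_max_nm <- calibration$r_max_um * 1000
  if (r_max_nm <= r0) abort("`r_max_um` must exceed the GNP radius.")
  edges <- seq(r0, r_max_nm, length.out = n_bins + 1L)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  shape <- mid^(-calibration$exponent)
  shell_mass_kg <- shell_masses_kg(edges)
  target_j <- calibration$eta * gnp_gold_mass(diameter_nm, "kg") # x 1 Gy
  scale <- target_j / sum(shape * shell_mass_kg)
  new_radial_dose_kernel(diameter_nm, edges, scale * shape, calibration)
}

# Water mass (kg) of the spherical shells delimited by `edges_nm`.
shell_masses_kg <- function(edges_nm) {
  vol_nm3 <- (4 / 3) * pi * diff(edges_nm^3)
  vol_nm3 * NM3_TO_G_WATER * WATER_DENSITY_G_CM3 * 1e-3
}

#' Shell-integrated kernel energy
#'
#' Total energy (joules) deposited in water per GNP per 1 Gy prescribed,
#' obtained by summing dose x shell water mass over the kernel bins.
#'
#' @param kernel A `radial_dose_kernel`.
#' @return Energy in joules.
#' @export
kernel_total_energy_j <- function(kernel) {
  stopifnot(inherits(kernel, "radial_dose_kernel"))
  sum(kernel$dose_gy_per_gy * shell_masses_kg(kernel$bin_edges_nm))
}

#' Query a kernel at radial distances
#'
#' Piecewise-constant lookup: radii inside the first edge return the first
#' bin's dose; radii at or beyond the last edge return exactly 0.
#'
#' @param kernel A `radial_dose_kernel`.
#' @param r_nm Radial distances in nanometres (>= 0); vectorised.
#' @return Excess dose in Gy per GNP per Gy prescribed, same length as `r_nm`.
#' @examples
#' k <- make_power_law_kernel(10)
#' kernel_dose_at(k, c(10, 1000, 6000))
#' @export
kernel_dose_at <- function(kernel, r_nm) {
  stopifnot(inherits(kernel, "radial_dose_kernel"))
  if (any(r_nm < 0)) abort("`r_nm` must be non-negative.")
  edges <- kernel$bin_edges_nm
  n <- length(kernel$dose_gy_per_gy)
  idx <- findInterval(r_nm, edges, rightmost.closed = FALSE)
  out <- numeric(length(r_nm))
  inside <- idx >= 1L & idx <= n
  out[inside] <- kernel$dose_gy_per_gy[idx[inside]]
  out[idx == 0L] <- kernel$dose_gy_per_gy[1L]
  out[r_nm >= edges[n + 1L]] <- 0
  out
}

#' @export
print.radial_dose_kernel <- function(x, ...) {
  cal <- x$calibration
  cat(sprintf(
    "<radial_dose_kernel> %g nm GNP, %d bins, %g-%g nm\n",
    x$diameter_nm, length(x$dose_gy_per_gy),
    x$bin_edges_nm[1], x$bin_edges_nm[length(x$bin_edges_nm)]
  ))
  cat(sprintf(
    "  eta = %g, exponent = %g, energy = %.3e J per GNP per Gy\n",
    cal$eta, cal$exponent, kernel_total_energy_j(x)
  ))
  invisible(x)
}

#' Tabulate a kernel as a tibble
#'
#' @param x A `radial_dose_kernel`.
#' @param ... Unused.
#' @return A tibble with columns `r_lo_nm`, `r_hi_nm`, `r_mid_nm`,
#'   `dose_gy_per_gy`.
#' @method tidy radial_dose_kernel
#' @export
tidy.radial_dose_kernel <- function(x, ...) {
  edges <- x$bin_edges_nm
  tibble(
    r_lo_nm = edges[-length(edges)],
    r_hi_nm = edges[-1],
    r_mid_nm = (edges[-1] + edges[-length(edges)]) / 2,
    dose_gy_per_gy = x$dose_gy_per_gy
  )
}
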