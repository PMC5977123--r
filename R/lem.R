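#' Linear-quadratic response parameters
#'
#' Defaults are the 6 MV photon response of the modelled breast-cancer cell
#' line: alpha = 0.002 / Gy, beta = 0.079 / Gy^2.
#'
#' @param alpha Linear coefficient (1/Gy, >= 0).
#' @param beta Quadratic coefficient (1/Gy^2, >= 0).
#' @return A list of class `"lq_params"`.
#' @export
lq_params <- function(alpha = 0.002, beta = 0.079) {
  if (alpha < 0 || beta < 0) abort("`alpha` and `beta` must be non-negative.")
  structure(list(alpha = alpha, beta = beta), class = "lq_params")
}

#' Closed-form linear-quadratic survival at a uniform dose
#'
#' @param dose_gy Uniform dose in Gy.
#' @param lq An [lq_params()].
#' @return Survival fraction `exp(-(alpha * D + beta * D^2))`.
#' @examples
#' lq_survival(2)  # exp(-0.32) = 0.7262
#' @export
lq_survival <- function(dose_gy, lq = lq_params()) {
  exp(-(lq$alpha * dose_gy + lq$beta * dose_gy^2))
}

#' Superpose per-GNP radial doses onto nucleus integration points
#'
#' Draws `n_points` integration points uniformly in the nucleus and, for
#' each point, sums the kernel dose of every GNP within the kernel range
#' using a grid cell-list radius query:
#' `dose_i = prescribed_dose * (1 + sum_j kernel(|p_i - g_j|))`.
#' The background beam dose is spatially uniform at `dose_gy`.
#'
#' @param placement A [sample_gnp_positions()] result (or any data frame
#'   with `x_um`, `y_um`, `z_um`).
#' @param kernel A [make_power_law_kernel()] kernel; its diameter must match
#'   the placement's.
#' @param geometry A [cell_geometry()].
#' @param dose_gy Prescribed macroscopic dose (Gy). Default 2.
#' @param n_points Nucleus integration points (>= 100). Default 10000.
#' @param seed Optional seed for the integration points.
#' @param method `"grid"` (cell-list radius query, default) or `"brute"`
#'   (all-pairs double loop); both give the same sums.
#' @return A tibble of class `"nucleus_dose"` with columns `x_um`, `y_um`,
#'   `z_um`, `dose_gy`.
#' @export
superpose_nucleus_dose <- function(placement,
                                   kernel,
                                   geometry = cell_geometry(),
                                   dose_gy = 2,
                                   n_points = 10000,
                                   seed = NULL,
                                   method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(kernel, "radial_dose_kernel"))
  if (dose_gy < 0) abort("`dose_gy` must be non-negative.")
  if (n_points < 100) abort("`n_points` must be at least 100.")
  pd <- attr(placement, "gnp_diameter_nm")
  if (!is.null(pd) && abs(pd - kernel$diameter_nm) > 1e-9) {
    abort(sprintf(
      "Kernel diameter (%g nm) does not match placement diameter (%g nm).",
      kernel$diameter_nm, pd
    ))
  }

  pts <- with_optional_seed(seed, sample_nucleus_points(n_points, geometry))
  excess <- nucleus_excess_factor(pts, placement, kernel, method)
  structure(
    tibble(
      x_um = pts$x_um, y_um = pts$y_um, z_um = pts$z_um,
      dose_gy = dose_gy * (1 + excess)
    ),
    prescribed_dose_gy = dose_gy,
    class = c("nucleus_dose", class(pts))
  )
}

sample_nucleus_points <- function(n, geometry) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  nrm <- sqrt(rowSums(u^2))
  r <- geometry$nucleus_radius_um * runif(n)^(1 / 3)
  tibble(x_um = u[, 1] / nrm * r, y_um = u[, 2] / nrm * r, z_um = u[, 3] / nrm * r)
}

# Dimensionless excess (sum over GNPs of kernel dose per Gy prescribed).
nucleus_excess_factor <- function(points, placement, kernel, method = "grid") {
  edges <- kernel$bin_edges_nm
  uniform <- length(edges) > 2 &&
    max(abs(diff(diff(edges)))) < 1e-9 * (edges[2] - edges[1])
  .superpose_excess_cpp(
    points$x_um, points$y_um, points$z_um,
    placement$x_um, placement$y_um, placement$z_um,
    edges, kernel$dose_gy_per_gy, uniform,
    if (method == "grid") 0L else 1L
  )
}

#' Local-effect-model survival from a heterogeneous nuclear dose
#'
#' The lethal-event density is the spatial mean of the linear-quadratic
#' response over the nucleus, `N = mean(alpha * d_i + beta * d_i^2)`, and
#' `SF = exp(-N)`. For a uniform dose field this reduces exactly to the
#' closed-form LQ survival; by Jensen's inequality a heterogeneous field
#' with the same mean dose gives a lower survival when beta > 0.
#'
#' @param dose A `nucleus_dose` tibble (uses its `dose_gy` column) or a
#'   numeric vector of local doses in Gy.
#' @param lq An [lq_params()].
#' @return Survival fraction in (0, 1].
#' @examples
#' lem_survival_fraction(rep(2, 100))  # = lq_survival(2)
#' @export
lem_survival_fraction <- function(dose, lq = lq_params()) {
  d <- if (is.data.frame(dose)) dose$dose_gy else dose
  if (length(d) == 0) abort("`dose` must be non-empty.")
  if (any(d < 0)) abort("Doses must be non-negative.")
  exp(-mean(lq$alpha * d + lq$beta * d^2))
}

#' Percent reduction in survival fraction
#'
#' @param sf_gnp Survival fraction with GNPs (0, 1].
#' @param sf_bg Background survival fraction (0, 1].
#' @return `100 * (1 - sf_gnp / sf_bg)`.
#' @examples
#' sf_reduction_percent(0.25, 0.31)  # 19.4
#' @export
sf_reduction_percent <- function(sf_gnp, sf_bg) {
  if (any(sf_bg <= 0)) abort("`sf_bg` must be positive.")
  if (any(sf_gnp <= 0 | sf_gnp > 1) || any(sf_bg > 1)) {
    abort("Survival fractions must lie in (0, 1].")
  }
  100 * (1 - sf_gnp / sf_bg)
}

#' Run the GNP-LEM pipeline over scenarios and seeds
#'
#' For each scenario and seed: sample a GNP placement, superpose the kernel
#' dose onto fresh nucleus integration points, and convert to survival.
#' The no-GNP baseline is the closed-form LQ survival at the prescribed
#' dose.
#'
#' @param scenarios Character vector of placement scenarios.
#' @param n_gnp Internalized GNP count per cell. Default 367000.
#' @param gnp_diameter_nm GNP diameter (nm). Default 10.
#' @param kernel Optional `radial_dose_kernel`; by default a power-law
#'   kernel calibrated to `gnp_diameter_nm` via `calibration`.
#' @param calibration A [kernel_calibration()] used when `kernel` is NULL.
#' @param geometry A [cell_geometry()].
#' @param lq An [lq_params()].
#' @param dose_gy Prescribed dose (Gy). Default 2.
#' @param n_points Nucleus integration points per run. Default 10000.
#' @param seeds Integer vector of seeds; one pipeline run per seed.
#' @param decay_length_um Perinuclear decay length (um). Default 1.
#' @param vesicle A [vesicle_spec()].
#' @return A tibble of class `"gnp_lem_study"` with one row per
#'   (scenario, seed): `scenario`, `diameter_nm`, `n_gnp`, `seed`, `sf_bg`,
#'   `sf_gnp`, `reduction_pct`.
#' @seealso [tidy.gnp_lem_study()], [glance.gnp_lem_study()]
#' @export
run_lem_study <- function(scenarios = c("uniform_cytoplasm", "perinuclear", "vesicle"),
                          n_gnp = 367000,
                          gnp_diameter_nm = 10,
                          kernel = NULL,
                          calibration = kernel_calibration(),
                          geometry = cell_geometry(),
                          lq = lq_params(),
                          dose_gy = 2,
                          n_points = 10000,
                          seeds = 1:3,
                          decay_length_um = 1,
                          vesicle = vesicle_spec()) {
  if (is.null(kernel)) {
    kernel <- make_power_law_kernel(gnp_diameter_nm, calibration)
  }
  sf_bg <- lq_survival(dose_gy, lq)
  grid <- tidyr::expand_grid(scenario = scenarios, seed = as.integer(seeds))
  rows <- purrr::pmap(grid, function(scenario, seed) {
    run <- with_optional_seed(seed, {
      placement <- sample_gnp_positions(
        n_gnp, scenario,
        geometry = geometry, gnp_diameter_nm = gnp_diameter_nm,
        decay_length_um = decay_length_um, vesicle = vesicle
      )
      superpose_nucleus_dose(placement, kernel, geometry, dose_gy, n_points)
    })
    sf_gnp <- lem_survival_fraction(run, lq)
    tibble(
      scenario = scenario, diameter_nm = gnp_diameter_nm,
      n_gnp = n_gnp, seed = seed,
      sf_bg = sf_bg, sf_gnp = sf_gnp,
      reduction_pct = sf_reduction_percent(sf_gnp, sf_bg)
    )
  })
  structure(
    dplyr::bind_rows(rows),
    class = c("gnp_lem_study", class(grid))
  )
}

#' Per-scenario summary of a GNP-LEM study
#'
#' @param x A [run_lem_study()] result.
#' @param ... Unused.
#' @return One row per scenario with the mean and SD of the percent SF
#'   reduction over seeds.
#' @method tidy gnp_lem_study
#' @export
tidy.gnp_lem_study <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(x), .data$scenario, .data$diameter_nm, .data$n_gnp),
    n_seeds = dplyr::n(),
    mean_reduction_pct = mean(.data$reduction_pct),
    sd_reduction_pct = if (dplyr::n() > 1) sd(.data$reduction_pct) else NA_real_,
    .groups = "drop"
  )
}

#' One-row summary of a GNP-LEM study
#'
#' @param x A [run_lem_study()] result.
#' @param ... Unused.
#' @return A one-row tibble: the maximum scenario-averaged percent SF
#'   reduction and the scenario attaining it.
#' @method glance gnp_lem_study
#' @export
glance.gnp_lem_study <- function(x, ...) {
  per <- tidy(x)
  best <- per[which.max(per$mean_reduction_pct), ]
  tibble(
    max_reduction_pct = best$mean_reduction_pct,
    best_scenario = best$scenario,
    diameter_nm = best$diameter_nm,
    n_scenarios = nrow(per),
    n_seeds = best$n_seeds
  )
}
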