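# Independent oracles, kept deliberately naive.

# Brute-force all-pairs dose superposition in plain R: for each point, sum
# kernel_dose_at over every GNP and scale by the prescribed dose.
oracle_superpose <- function(points, placement, kernel, dose_gy = 2) {
  vapply(seq_len(nrow(points)), function(i) {
    r_nm <- 1000 * sqrt(
      (points$x_um[i] - placement$x_um)^2 +
        (points$y_um[i] - placement$y_um)^2 +
        (points$z_um[i] - placement$z_um)^2
    )
    dose_gy * (1 + sum(kernel_dose_at(kernel, r_nm)))
  }, numeric(1))
}

# Shell-quadrature kernel energy: integrate dose(r) * 4 pi r^2 rho dr on a
# fine sub-grid of each bin (piecewise-constant, so the sub-grid makes this
# plain Riemann quadrature independent of the shell-mass formula).
oracle_kernel_energy_j <- function(kernel, n_sub = 50) {
  edges <- kernel$bin_edges_nm
  total <- 0
  for (b in seq_along(kernel$dose_gy_per_gy)) {
    r <- seq(edges[b], edges[b + 1], length.out = n_sub + 1)
    mid <- (r[-1] + r[-length(r)]) / 2
    dr <- diff(r)
    # water mass density: 1e-21 g/nm^3 -> 1e-24 kg/nm^3
    total <- total + sum(kernel$dose_gy_per_gy[b] * 4 * pi * mid^2 * dr * 1e-24)
  }
  total
}

# Two-sided permutation p-value for a difference in means.
oracle_permutation_p <- function(x, y, n_perm = 40000) {
  obs <- abs(mean(x) - mean(y))
  pooled <- c(x, y)
  nx <- length(x)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), nx)
    if (abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

in_cytoplasm <- function(p, geom = cell_geometry()) {
  r <- sqrt(p$x_um^2 + p$y_um^2 + p$z_um^2)
  inside <- (p$x_um / geom$semi_axis_a_um)^2 +
    (p$y_um / geom$semi_axis_b_um)^2 +
    (p$z_um / geom$semi_axis_c_um)^2 <= 1 + 1e-12
  inside & r >= geom$nucleus_radius_um - 1e-12
}
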