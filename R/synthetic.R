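#' Study design for the synthetic clonogenic experiment
#'
#' Eight arms — four agents (saline, GNP-RGD, CIS, GNP-RGD;CIS) crossed with
#' 0 Gy and 2 Gy — with the measured survival fractions of the emulated
#' study as the generating truths: 1.0 and 1.0 (saline, GNP-RGD unirradiated;
#' the GNP construct alone is non-toxic), 0.61 (CIS), 0.60 (GNP-RGD;CIS),
#' 0.31 (irradiated saline), 0.25 (irradiated GNP-RGD), 0.23 (irradiated
#' CIS), 0.16 (irradiated GNP-RGD;CIS). Nine plates per arm mirror the
#' n = 9 cell preparations of the emulated assays.
#'
#' @param true_sf Named-by-position vector of 8 generating survival
#'   fractions, ordered as the default `conditions` x `dose_gy` grid.
#' @param pe Plating efficiency in (0, 1]. Default 0.5.
#' @param plates_per_condition Replicate plates per arm. Default 9.
#' @param cells_plated Cells seeded per plate. Default 400.
#' @return A tibble of class `"study_design"`: `condition`, `dose_gy`,
#'   `label`, `true_sf`, `pe`, `plates`, `cells_plated`.
#' @export
study_design <- function(true_sf = c(1.0, 1.0, 0.61, 0.60, 0.31, 0.25, 0.23, 0.16),
                         pe = 0.5,
                         plates_per_condition = 9,
                         cells_plated = 400) {
  if (length(true_sf) != 8) abort("`true_sf` must have 8 values.")
  if (any(true_sf < 0 | true_sf > 1)) abort("`true_sf` must lie in [0, 1].")
  if (pe <= 0 || pe > 1) abort("`pe` must lie in (0, 1].")
  conditions <- c("saline", "GNP-RGD", "CIS", "GNP-RGD;CIS")
  grid <- tidyr::expand_grid(dose_gy = c(0, 2), condition = conditions)
  out <- tibble(
    condition = grid$condition,
    dose_gy = grid$dose_gy,
    label = paste0(grid$condition, ifelse(grid$dose_gy > 0, " + IR", "")),
    true_sf = true_sf,
    pe = pe,
    plates = as.integer(plates_per_condition),
    cells_plated = as.integer(cells_plated)
  )
  structure(out, class = c("study_design", class(out)))
}

#' Generate synthetic clonogenic colony counts
#'
#' Each plate's colony count is drawn as
#' `Binomial(cells_plated, pe x true_sf)` — the simplest mechanism
#' consistent with the plating-efficiency and survival-fraction
#' definitions. An optional beta-binomial overdispersion hook is provided
#' but off by default.
#'
#' @param design A [study_design()].
#' @param seed Optional integer seed.
#' @param overdispersion Beta-binomial intra-plate correlation rho in
#'   `[0, 1)`; 0 (default) gives pure binomial sampling.
#' @return A tibble with columns `condition`, `dose_gy`, `label`,
#'   `replicate`, `cells_plated`, `colonies`.
#' @export
gen_colony_counts <- function(design = study_design(), seed = NULL,
                              overdispersion = 0) {
  if (any(design$pe * design$true_sf > 1)) {
    abort("`pe * true_sf` must not exceed 1.")
  }
  if (overdispersion < 0 || overdispersion >= 1) {
    abort("`overdispersion` must lie in [0, 1).")
  }
  with_optional_seed(seed, {
    purrr::pmap_dfr(design, function(condition, dose_gy, label, true_sf, pe,
                                     plates, cells_plated, ...) {
      p <- pe * true_sf
      prob <- if (overdispersion > 0 && p > 0 && p < 1) {
        shape <- (1 - overdispersion) / overdispersion
        stats::rbeta(plates, p * shape, (1 - p) * shape)
      } else {
        rep(p, plates)
      }
      tibble(
        condition = condition, dose_gy = dose_gy, label = label,
        replicate = seq_len(plates),
        cells_plated = cells_plated,
        colonies = rbinom(plates, cells_plated, prob)
      )
    })
  })
}

#' Generate synthetic per-cell gold-mass measurements
#'
#' Emulates elemental-analysis uptake data: per-cell GNP counts for the
#' three constructs (unmodified GNP, peptide-modified GNP-RGD, and GNP-RGD
#' with cisplatin) with means 56,000, 358,000 and 367,000 GNPs/cell,
#' converted to gold mass and jittered with mean-preserving lognormal noise.
#' Whether the printed spreads are SDs or SEMs is ambiguous in the emulated
#' study; both interpretations are available.
#'
#' @param samples A tibble with columns `sample`, `mean_count`,
#'   `spread_count`; defaults to the three constructs above with printed
#'   spreads 1200, 47000, 6600.
#' @param n Replicates per sample. Default 3.
#' @param diameter_nm GNP diameter (nm). Default 10.
#' @param spread `"sd"` (default) treats `spread_count` as a standard
#'   deviation; `"sem"` scales it by `sqrt(n)` first.
#' @param seed Optional integer seed.
#' @return A tibble: `sample`, `replicate`, `diameter_nm`,
#'   `au_mass_g_per_cell`.
#' @export
gen_uptake_measurements <- function(samples = default_uptake_samples(),
                                    n = 3,
                                    diameter_nm = 10,
                                    spread = c("sd", "sem"),
                                    seed = NULL) {
  spread <- match.arg(spread)
  if (any(samples$spread_count < 0)) abort("`spread_count` must be >= 0.")
  m1 <- gnp_gold_mass(diameter_nm, "g")
  with_optional_seed(seed, {
    purrr::pmap_dfr(samples, function(sample, mean_count, spread_count, ...) {
      sd_count <- if (spread == "sem") spread_count * sqrt(n) else spread_count
      cv <- sd_count / mean_count
      counts <- if (cv == 0) {
        rep(mean_count, n)
      } else {
        sdlog <- sqrt(log(1 + cv^2))
        rlnorm(n, meanlog = log(mean_count) - sdlog^2 / 2, sdlog = sdlog)
      }
      tibble(
        sample = sample, replicate = seq_len(n),
        diameter_nm = diameter_nm,
        au_mass_g_per_cell = counts * m1
      )
    })
  })
}

#' @rdname gen_uptake_measurements
#' @export
default_uptake_samples <- function() {
  tibble(
    sample = c("GNP", "GNP-RGD", "GNP-RGD;CIS"),
    mean_count = c(56000, 358000, 367000),
    spread_count = c(1200, 47000, 6600)
  )
}

#' Generate synthetic DNA double-strand-break focus counts
#'
#' Per-nucleus projected areas are lognormal (positive and right-skewed,
#' median `area_median_um2`) and focus counts are Poisson with mean
#' `density x area`, emulating the irradiated-arm focus densities of the
#' modelled study: 0.024 (saline), 0.026 (GNP-RGD), 0.026 (CIS) and 0.040
#' (GNP-RGD;CIS) foci per um^2, with 274 / 310 / 307 / 357 nuclei.
#'
#' @param densities Named numeric vector of generating densities
#'   (foci per um^2).
#' @param n_nuclei Integer vector of nuclei per condition, recycled against
#'   `densities`.
#' @param area_median_um2 Median projected nuclear area. Default 150.
#' @param area_sdlog Lognormal sdlog of the areas. Default 0.35.
#' @param seed Optional integer seed.
#' @return A tibble: `condition`, `nucleus_id`, `area_um2`, `foci_count`.
#' @export
gen_foci_counts <- function(densities = c("IR saline" = 0.024,
                                          "IR GNP-RGD" = 0.026,
                                          "IR CIS" = 0.026,
                                          "IR GNP-RGD;CIS" = 0.040),
                            n_nuclei = c(274, 310, 307, 357),
                            area_median_um2 = 150,
                            area_sdlog = 0.35,
                            seed = NULL) {
  if (any(densities < 0)) abort("`densities` must be >= 0.")
  n_nuclei <- rep_len(n_nuclei, length(densities))
  labels <- if (is.null(names(densities))) as.character(densities) else names(densities)
  with_optional_seed(seed, {
    purrr::pmap_dfr(
      list(labels, densities, n_nuclei),
      function(lab, dens, n) {
        area <- rlnorm(n, meanlog = log(area_median_um2), sdlog = area_sdlog)
        tibble(
          condition = lab,
          nucleus_id = seq_len(n),
          area_um2 = area,
          foci_count = rpois(n, dens * area)
        )
      }
    )
  })
}

#' Generate synthetic TEM core-diameter measurements
#'
#' Normal draws truncated at zero (by resampling), emulating a TEM sizing
#' series of 10.04 +/- 0.89 nm (mean +/- SD, n = 50).
#'
#' @param mean_nm Mean diameter. Default 10.04.
#' @param sd_nm Standard deviation. Default 0.89.
#' @param n Number of particles measured. Default 50.
#' @param seed Optional integer seed.
#' @return A numeric vector of `n` diameters (nm), all positive.
#' @export
gen_tem_diameters <- function(mean_nm = 10.04, sd_nm = 0.89, n = 50, seed = NULL) {
  if (sd_nm < 0) abort("`sd_nm` must be >= 0.")
  with_optional_seed(seed, {
    d <- rnorm(n, mean_nm, sd_nm)
    while (any(d <= 0)) {
      bad <- d <= 0
      d[bad] <- rnorm(sum(bad), mean_nm, sd_nm)
    }
    d
  })
}

#' Experiment metadata of the emulated protocol
#'
#' Concentrations and construct stoichiometry carried as provenance into
#' synthetic outputs: 0.3 nM GNPs, 435 nM cisplatin, ~620 cisplatin
#' molecules per GNP, ~300 stabilising CALNN peptides and 16-20 RGD
#' peptides per GNP, 16 h incubation.
#'
#' @return A one-row tibble of metadata constants.
#' @export
experiment_metadata <- function() {
  tibble(
    gnp_concentration_nM = 0.3,
    cisplatin_concentration_nM = 435,
    cisplatin_per_gnp = 620,
    calnn_per_gnp = 300,
    rgd_per_gnp_min = 16,
    rgd_per_gnp_max = 20,
    incubation_h = 16
  )
}
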