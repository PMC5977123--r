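#' Clonogenic plating efficiency
#'
#' Pooled over control plates: total colonies counted divided by total cells
#' plated. Pooling (rather than averaging per-plate ratios) follows the
#' count-level definition of the assay.
#'
#' @param plates A data frame of control plates with columns `cells_plated`
#'   and `colonies` (one row per plate).
#' @return Plating efficiency in `[0, 1]`.
#' @examples
#' plating_efficiency(data.frame(cells_plated = c(100, 100), colonies = c(50, 50)))
#' @export
plating_efficiency <- function(plates) {
  check_plates(plates)
  if (nrow(plates) < 1) abort("At least one control plate is required.")
  plated <- sum(plates$cells_plated)
  if (plated == 0) abort("Total cells plated must be positive.")
  pe <- sum(plates$colonies) / plated
  if (pe == 0) {
    warn("Plating efficiency is 0; downstream survival fractions are undefined.")
  }
  pe
}

check_plates <- function(plates) {
  if (!all(c("cells_plated", "colonies") %in% names(plates))) {
    abort("`plates` must have columns `cells_plated` and `colonies`.")
  }
  if (any(plates$colonies < 0) || any(plates$cells_plated < 0)) {
    abort("Counts must be non-negative.")
  }
  if (any(plates$colonies > plates$cells_plated)) {
    abort("`colonies` cannot exceed `cells_plated`.")
  }
  invisible(plates)
}

#' Clonogenic survival fraction
#'
#' `SF = colonies / (cells plated x PE)`, applied per plate.
#'
#' @param plates A data frame of treated plates with columns `cells_plated`
#'   and `colonies`.
#' @param pe Plating efficiency from [plating_efficiency()] (> 0).
#' @return The input as a tibble with an added `sf` column.
#' @examples
#' survival_fraction(data.frame(cells_plated = 400, colonies = 50), pe = 0.5)
#' @export
survival_fraction <- function(plates, pe) {
  check_plates(plates)
  if (length(pe) != 1 || pe <= 0) abort("`pe` must be a single positive value.")
  dplyr::mutate(as_tibble(plates), sf = .data$colonies / (.data$cells_plated * pe))
}

#' Summarise replicate survival fractions as mean and standard error
#'
#' @param sf Numeric vector of replicate survival fractions, or a data
#'   frame with an `sf` column (e.g. from [survival_fraction()]).
#' @return A one-row tibble with `mean`, `sem` (sample SD / sqrt(n)), `n`.
#' @examples
#' summarize_sf(c(0.2, 0.3))  # mean 0.25, sem 0.05
#' @export
summarize_sf <- function(sf) {
  x <- if (is.data.frame(sf)) sf$sf else sf
  if (length(x) < 2) abort("At least two replicates are required for a SEM.")
  if (any(x < 0)) abort("Survival fractions must be non-negative.")
  tibble(mean = mean(x), sem = sd(x) / sqrt(length(x)), n = length(x))
}

#' Percent decrease in survival with propagated uncertainty
#'
#' `100 * (1 - b/a)` where `a` is the reference arm and `b` the treated arm,
#' with a first-order delta-method standard error on the ratio:
#' `se^2 = (100/a)^2 sem_b^2 + (100 b / a^2)^2 sem_a^2`.
#'
#' @param a Reference arm: a one-row data frame or list with `mean` and
#'   `sem` (e.g. from [summarize_sf()]).
#' @param b Treated arm, same form.
#' @return A one-row tibble with `percent` and `se`.
#' @examples
#' percent_decrease(list(mean = 0.31, sem = 0.008), list(mean = 0.25, sem = 0.014))
#' @export
percent_decrease <- function(a, b) {
  am <- a$mean; bm <- b$mean
  if (is.null(am) || is.null(bm)) abort("`a` and `b` need `mean` (and `sem`) fields.")
  if (am <= 0) abort("Reference mean must be positive.")
  asem <- if (is.null(a$sem)) 0 else a$sem
  bsem <- if (is.null(b$sem)) 0 else b$sem
  se <- sqrt((100 / am)^2 * bsem^2 + (100 * bm / am^2)^2 * asem^2)
  tibble(percent = 100 * (1 - bm / am), se = se)
}

#' DNA double-strand-break focus density per projected nuclear area
#'
#' Pooled density: total foci divided by total 2D projected nuclear area,
#' with a standard error computed from the spread of per-nucleus densities.
#'
#' @param foci A data frame with columns `foci_count` and `area_um2`
#'   (one row per nucleus).
#' @return A one-row tibble: `density` (foci per um^2), `sem`, `n_nuclei`.
#' @examples
#' foci_density(data.frame(foci_count = c(4, 6), area_um2 = c(100, 150)))
#' @export
foci_density <- function(foci) {
  if (!all(c("foci_count", "area_um2") %in% names(foci))) {
    abort("`foci` must have columns `foci_count` and `area_um2`.")
  }
  if (nrow(foci) < 1) abort("At least one nucleus is required.")
  if (any(foci$area_um2 <= 0)) abort("Nuclear areas must be positive.")
  if (any(foci$foci_count < 0)) abort("Focus counts must be non-negative.")
  total_area <- sum(foci$area_um2)
  per_cell <- foci$foci_count / foci$area_um2
  n <- nrow(foci)
  tibble(
    density = sum(foci$foci_count) / total_area,
    sem = if (n > 1) sd(per_cell) / sqrt(n) else NA_real_,
    n_nuclei = n
  )
}

#' GNPs per cell from measured gold mass
#'
#' Divides the per-cell gold mass by the mass of one gold sphere of the
#' stated diameter (bulk gold density 19.32 g/cm^3).
#'
#' @param gold_mass_g Gold mass per cell in grams (>= 0); vectorised.
#' @param diameter_nm GNP core diameter (nm).
#' @return GNP count per cell.
#' @examples
#' gnp_count_from_gold_mass(5.66e-13, 10)  # ~56,000
#' @export
gnp_count_from_gold_mass <- function(gold_mass_g, diameter_nm) {
  if (any(gold_mass_g < 0)) abort("`gold_mass_g` must be non-negative.")
  gold_mass_g / gnp_gold_mass(diameter_nm, "g")
}

#' Fold change between two counts
#'
#' @param a Reference count (> 0).
#' @param b Comparison count.
#' @return `b / a`.
#' @examples
#' fold_change(56000, 358000)  # 6.39
#' @export
fold_change <- function(a, b) {
  if (any(a <= 0)) abort("Reference count must be positive.")
  b / a
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sided t-test with Welch-Satterthwaite degrees of
#' freedom, returned as a tidy one-row tibble.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @return A tibble with `statistic`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("Each sample needs at least 2 values.")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(tibble(statistic = 0, df = NA_real_, p_value = 1,
                    mean_x = mean(x), mean_y = mean(y)))
    }
    abort("Both samples are degenerate (zero variance).")
  }
  fit <- stats::t.test(x, y, var.equal = FALSE)
  tibble(
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value,
    mean_x = mean(x),
    mean_y = mean(y)
  )
}

#' Full clonogenic analysis of a plate table
#'
#' Computes the plating efficiency from the control condition and per-plate
#' survival fractions for every condition, summarised as mean +/- SEM.
#'
#' Because every arm is normalised by the same estimated plating
#' efficiency, the replicate SEM alone understates the uncertainty of the
#' survival fraction as an absolute quantity: an error in PE shifts all
#' arms coherently. `sem_total` adds the PE uncertainty by the delta
#' method, `sem_total^2 = sem^2 + (mean x sem_pe / pe)^2`, and is the
#' appropriate scale when comparing a recovered SF against an external
#' truth; `sem` is the plain replicate standard error reported alongside
#' means in the assay literature.
#'
#' @param plates A data frame with columns `condition`, `cells_plated`,
#'   `colonies` (and optionally `replicate`).
#' @param control The condition label used for plating efficiency.
#' @return A tibble with one row per condition: `condition`, `mean`, `sem`,
#'   `n`, `sem_total`, plus attributes `pe` and `pe_sem`.
#' @export
clonogenic_analysis <- function(plates, control) {
  if (!"condition" %in% names(plates)) abort("`plates` must have a `condition` column.")
  check_plates(plates)
  ctrl <- plates[plates$condition == control, ]
  if (nrow(ctrl) == 0) abort(sprintf("No plates with control condition '%s'.", control))
  pe <- plating_efficiency(ctrl)
  pe_per_plate <- ctrl$colonies / ctrl$cells_plated
  pe_sem <- if (nrow(ctrl) > 1) sd(pe_per_plate) / sqrt(nrow(ctrl)) else 0
  scored <- survival_fraction(plates, pe)
  out <- dplyr::reframe(
    dplyr::group_by(scored, .data$condition),
    summarize_sf(.data$sf)
  )
  out <- dplyr::mutate(
    dplyr::ungroup(out),
    sem_total = sqrt(.data$sem^2 + (.data$mean * pe_sem / pe)^2)
  )
  structure(out, pe = pe, pe_sem = pe_sem)
}
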