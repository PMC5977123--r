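#' Bliss-independence expected survival fraction
#'
#' Under Bliss independence the effects of two agents combine as
#' `E_AB = E_A + E_B - E_A * E_B`; in survival terms the surviving
#' fractions multiply, `SF_AB = SF_A * SF_B`.
#'
#' @param sf_a,sf_b Marginal survival fractions in `[0, 1]`; vectorised.
#' @return Expected combination survival fraction.
#' @examples
#' bliss_expected_sf(0.61, 0.26)  # 0.1586
#' @export
bliss_expected_sf <- function(sf_a, sf_b) {
  if (any(sf_a < 0 | sf_a > 1) || any(sf_b < 0 | sf_b > 1)) {
    abort("Survival fractions must lie in [0, 1].")
  }
  sf_a * sf_b
}

#' Classify an observed combination against the Bliss expectation
#'
#' The call is `"additive"` when the observed mean lies within
#' `k_sigma x SEM` of the Bliss expectation, `"synergistic"` when the
#' observed survival is below that band (greater-than-independent killing),
#' and `"antagonistic"` when above it.
#'
#' @param expected Bliss-expected survival fraction (e.g. from
#'   [bliss_expected_sf()]).
#' @param observed Observed combination arm: a one-row data frame or list
#'   with `mean` and `sem`.
#' @param k_sigma Width of the additivity band in SEM units. Default 2.
#' @return A one-row tibble: `sf_expected`, `sf_observed`, `sem`,
#'   `k_sigma`, `call`.
#' @examples
#' bliss_classify(bliss_expected_sf(0.61, 0.26), list(mean = 0.16, sem = 0.007))
#' @export
bliss_classify <- function(expected, observed, k_sigma = 2) {
  sem <- observed$sem
  if (is.null(sem) || sem < 0) abort("`observed$sem` must be >= 0.")
  m <- observed$mean
  call <- if (abs(m - expected) <= k_sigma * sem) {
    "additive"
  } else if (m < expected) {
    "synergistic"
  } else {
    "antagonistic"
  }
  tibble(
    sf_expected = expected, sf_observed = m, sem = sem,
    k_sigma = k_sigma, call = call
  )
}

#' Expected surviving clonogens after fractionated treatment
#'
#' @param n0 Initial clonogen count (e.g. 1e12 for a macroscopic tumor).
#' @param sf Survival fraction per treatment, in (0, 1].
#' @param n Number of treatments (>= 0); vectorised.
#' @return Expected survivors `n0 * sf^n`.
#' @examples
#' survivors_after_fractions(1e12, 0.16, 16)
#' @export
survivors_after_fractions <- function(n0, sf, n) {
  if (any(n0 < 0)) abort("`n0` must be non-negative.")
  if (any(sf <= 0 | sf > 1)) abort("`sf` must lie in (0, 1].")
  if (any(n < 0)) abort("`n` must be non-negative.")
  n0 * sf^n
}

#' Poisson tumor control probability
#'
#' @param survivors Expected surviving clonogens (>= 0); vectorised.
#' @return `exp(-survivors)`.
#' @export
poisson_tcp <- function(survivors) {
  if (any(survivors < 0)) abort("`survivors` must be non-negative.")
  exp(-survivors)
}

#' Smallest number of fractions reaching a target TCP
#'
#' Brute-force scan over the number of treatments.
#'
#' @param n0 Initial clonogen count.
#' @param sf Survival fraction per treatment, in (0, 1].
#' @param target_tcp Target tumor control probability in (0, 1).
#' @param n_max Scan limit. Default 10000.
#' @return The smallest `n` with `exp(-n0 * sf^n) >= target_tcp`, or `NA`
#'   (with a warning) if unreachable within `n_max`.
#' @examples
#' min_fractions_for_tcp(1e12, 0.16, 0.5)  # 16
#' min_fractions_for_tcp(1e12, 0.23, 0.5)  # 20
#' @export
min_fractions_for_tcp <- function(n0, sf, target_tcp, n_max = 10000) {
  if (target_tcp <= 0 || target_tcp >= 1) abort("`target_tcp` must lie in (0, 1).")
  if (sf <= 0 || sf > 1) abort("`sf` must lie in (0, 1].")
  for (n in 0:n_max) {
    if (poisson_tcp(survivors_after_fractions(n0, sf, n)) >= target_tcp) {
      return(n)
    }
  }
  warn(sprintf("Target TCP %g not reached within %d fractions.", target_tcp, n_max))
  NA_integer_
}

#' Tabulate survivors and TCP over fraction numbers
#'
#' @param n0 Initial clonogen count.
#' @param sf Survival fraction per treatment, in (0, 1]; may be a named
#'   vector to compare schedules.
#' @param n_fractions Integer vector of treatment counts.
#' @return A tibble of class `"tcp_curve"` with columns `sf_per_treatment`,
#'   `n_treatments`, `survivors`, `tcp`.
#' @examples
#' tcp_curve(1e12, c(IR_CIS = 0.23, IR_GNP_CIS = 0.16), 0:25)
#' @export
tcp_curve <- function(n0, sf, n_fractions = 0:30) {
  labels <- if (is.null(names(sf))) as.character(sf) else names(sf)
  out <- purrr::map2_dfr(sf, labels, function(s, lab) {
    surv <- survivors_after_fractions(n0, s, n_fractions)
    tibble(
      schedule = lab, sf_per_treatment = s, n_treatments = n_fractions,
      survivors = surv, tcp = poisson_tcp(surv)
    )
  })
  structure(out, n0 = n0, class = c("tcp_curve", class(out)))
}
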