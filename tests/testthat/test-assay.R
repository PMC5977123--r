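test_that("plating efficiency pools colonies over plates", {
  expect_equal(
    plating_efficiency(data.frame(cells_plated = 200, colonies = 100)), 0.5
  )
  expect_equal(
    plating_efficiency(data.frame(cells_plated = c(100, 100), colonies = c(50, 50))),
    0.5
  )
  expect_warning(
    pe0 <- plating_efficiency(data.frame(cells_plated = 100, colonies = 0)),
    "undefined"
  )
  expect_equal(pe0, 0)
  expect_error(
    plating_efficiency(data.frame(cells_plated = 10, colonies = 11)),
    "exceed"
  )
})

test_that("survival fraction follows colonies / (plated x PE)", {
  sf <- survival_fraction(data.frame(cells_plated = 400, colonies = 50), pe = 0.5)
  expect_equal(sf$sf, 0.25)
  sf1 <- survival_fraction(data.frame(cells_plated = 100, colonies = 50), pe = 0.5)
  expect_equal(sf1$sf, 1)
  expect_error(
    survival_fraction(data.frame(cells_plated = 1, colonies = 1), pe = 0),
    "positive"
  )
})

test_that("replicate summaries give mean and SEM", {
  s <- summarize_sf(c(0.2, 0.3))
  expect_equal(s$mean, 0.25)
  expect_equal(s$sem, 0.05)
  expect_equal(summarize_sf(rep(0.4, 5))$sem, 0)
  expect_error(summarize_sf(0.5), "two replicates")
})

test_that("percent decrease and its delta-method error match hand calculation", {
  d1 <- percent_decrease(
    list(mean = 0.31, sem = 0.008),
    list(mean = 0.25, sem = 0.014)
  )
  expect_equal(d1$percent, 19.35, tolerance = 1e-3)
  expect_equal(
    d1$se,
    sqrt((100 / 0.31 * 0.014)^2 + (100 * 0.25 / 0.31^2 * 0.008)^2),
    tolerance = 1e-12
  )
  expect_equal(round(d1$se, 1), 5.0)

  d2 <- percent_decrease(
    list(mean = 0.23, sem = 0.011),
    list(mean = 0.16, sem = 0.007)
  )
  expect_equal(d2$percent, 30.43, tolerance = 1e-2)
  expect_equal(round(d2$se, 1), 4.5)

  expect_equal(percent_decrease(list(mean = 0.3), list(mean = 0.3))$percent, 0)
  expect_error(percent_decrease(list(mean = 0), list(mean = 0.1)), "positive")
})

test_that("focus density pools counts over pooled area", {
  one <- foci_density(data.frame(foci_count = 4, area_um2 = 100))
  expect_equal(one$density, 0.04)
  two <- data.frame(foci_count = c(3, 5), area_um2 = c(120, 180))
  expect_equal(foci_density(two)$density, 8 / 300)
  # doubling every area halves the density
  halved <- foci_density(transform(two, area_um2 = 2 * area_um2))
  expect_equal(halved$density, foci_density(two)$density / 2)
  expect_error(foci_density(data.frame(foci_count = 1, area_um2 = 0)), "positive")
})

test_that("gold mass converts to GNP counts through the sphere mass", {
  expect_equal(gnp_count_from_gold_mass(1.0116e-17, 10), 1, tolerance = 1e-3)
  expect_equal(gnp_count_from_gold_mass(5.66e-13, 10), 56000, tolerance = 0.01)
  expect_equal(gnp_count_from_gold_mass(0, 10), 0)
  # round trip
  expect_equal(gnp_count_from_gold_mass(56000 * gnp_gold_mass(10), 10), 56000)
})

test_that("fold change reproduces the 6-7x uptake improvement", {
  expect_equal(fold_change(56000, 358000), 6.39, tolerance = 1e-3)
  expect_equal(fold_change(56000, 367000), 6.55, tolerance = 1e-3)
  expect_equal(fold_change(3, 3), 1)
  expect_error(fold_change(0, 1), "positive")
})

test_that("Welch test behaves at the extremes and near a permutation oracle", {
  same <- c(0.2, 0.3, 0.25)
  expect_equal(welch_t_test(same, same)$p_value, 1, tolerance = 1e-12)
  far <- welch_t_test(c(0.1, 0.11, 0.12), c(10, 10.1, 10.2))
  # df ~ 2 for n = 3 per arm, so the p-value is small but not astronomical
  expect_lt(far$p_value, 1e-3)
  expect_error(welch_t_test(c(1, 1), c(2, 2)), "degenerate")

  set.seed(401)
  x <- rnorm(9, 0.31, 0.03)
  y <- rnorm(9, 0.26, 0.03)
  p_w <- welch_t_test(x, y)$p_value
  set.seed(402)
  p_perm <- oracle_permutation_p(x, y)
  expect_lt(abs(p_w - p_perm), 0.02)
})

test_that("estimators are invariant to record ordering", {
  set.seed(17)
  plates <- data.frame(
    cells_plated = rep(400, 6),
    colonies = rbinom(6, 400, 0.2)
  )
  shuffled <- plates[sample(nrow(plates)), ]
  expect_equal(plating_efficiency(shuffled), plating_efficiency(plates))
  foci <- data.frame(foci_count = rpois(20, 4), area_um2 = runif(20, 80, 200))
  expect_equal(
    foci_density(foci[sample(nrow(foci)), ])$density,
    foci_density(foci)$density
  )
})

test_that("clonogenic_analysis recovers per-condition summaries from plate tables", {
  design <- study_design()
  plates <- gen_colony_counts(design, seed = 88)
  # one analysis arm per agent x dose label, PE from unirradiated saline
  arms <- dplyr::transmute(plates,
    condition = label,
    cells_plated = cells_plated, colonies = colonies
  )
  res <- clonogenic_analysis(arms, control = "saline")
  expect_equal(nrow(res), 8)
  expect_true(all(res$n == 9))
  expect_gt(attr(res, "pe"), 0)
  expect_error(clonogenic_analysis(arms, control = "nope"), "control")
})
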