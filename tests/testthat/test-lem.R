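test_that("LEM on a uniform dose field equals closed-form LQ survival", {
  expect_equal(lem_survival_fraction(rep(2, 1000)), exp(-0.32), tolerance = 1e-12)
  expect_equal(round(lq_survival(2), 5), 0.72615)
  expect_equal(lem_survival_fraction(rep(0, 10)), 1)
  # arbitrary LQ parameters
  lq <- lq_params(alpha = 0.15, beta = 0.05)
  expect_equal(lem_survival_fraction(rep(3, 7), lq), lq_survival(3, lq))
})

test_that("dose heterogeneity at fixed mean dose lowers LEM survival (Jensen)", {
  uniform <- rep(2, 1000)
  two_level <- rep(c(1, 3), 500) # same mean
  expect_lt(lem_survival_fraction(two_level), lem_survival_fraction(uniform))
})

test_that("empty placements leave the prescribed dose untouched", {
  k <- make_power_law_kernel(10)
  empty <- sample_gnp_positions(0, "uniform_cytoplasm", seed = 1)
  nd <- superpose_nucleus_dose(empty, k, n_points = 200, seed = 2)
  expect_true(all(nd$dose_gy == 2))
  expect_equal(lem_survival_fraction(nd), lq_survival(2))
})

test_that("every nucleus dose is at least the prescribed dose, points inside nucleus", {
  k <- make_power_law_kernel(10)
  p <- sample_gnp_positions(2000, "perinuclear", seed = 4)
  nd <- superpose_nucleus_dose(p, k, dose_gy = 2, n_points = 500, seed = 5)
  expect_true(all(nd$dose_gy >= 2))
  expect_true(all(sqrt(nd$x_um^2 + nd$y_um^2 + nd$z_um^2) <= 4 + 1e-12))
})

test_that("a single GNP contributes exactly one kernel lookup per point", {
  k <- make_power_law_kernel(10)
  one <- tibble::tibble(x_um = 0, y_um = 5, z_um = 0) # 1 um from (0,4,0)
  nd <- superpose_nucleus_dose(one, k, dose_gy = 2, n_points = 300, seed = 8)
  r_nm <- 1000 * sqrt(nd$x_um^2 + (nd$y_um - 5)^2 + nd$z_um^2)
  expect_equal(nd$dose_gy, 2 * (1 + kernel_dose_at(k, r_nm)), tolerance = 1e-15)
})

test_that("grid-indexed superposition matches the brute-force R oracle", {
  k <- make_power_law_kernel(10)
  p <- sample_gnp_positions(100, "uniform_cytoplasm", seed = 21)
  nd <- superpose_nucleus_dose(p, k, n_points = 100, seed = 22, method = "grid")
  oracle <- oracle_superpose(nd, p, k, dose_gy = 2)
  expect_lt(max(abs(nd$dose_gy - oracle) / oracle), 1e-12)
  # the compiled brute-force path agrees too
  ndb <- superpose_nucleus_dose(p, k, n_points = 100, seed = 22, method = "brute")
  expect_lt(max(abs(nd$dose_gy - ndb$dose_gy) / ndb$dose_gy), 1e-12)
})

test_that("indexed and brute-force paths agree on a 1000-GNP instance", {
  k <- make_power_law_kernel(10)
  p <- sample_gnp_positions(1000, "vesicle", seed = 31)
  g <- superpose_nucleus_dose(p, k, n_points = 200, seed = 32, method = "grid")
  b <- superpose_nucleus_dose(p, k, n_points = 200, seed = 32, method = "brute")
  expect_lt(max(abs(g$dose_gy - b$dose_gy) / b$dose_gy), 1e-12)
})

test_that("kernel/placement diameter mismatch is rejected", {
  k <- make_power_law_kernel(10)
  p <- sample_gnp_positions(10, "uniform_cytoplasm", gnp_diameter_nm = 2, seed = 1)
  expect_error(superpose_nucleus_dose(p, k), "does not match")
})

test_that("survival-fraction reduction arithmetic matches the measured arms", {
  expect_equal(round(sf_reduction_percent(0.25, 0.31)), 19)
  expect_equal(round(sf_reduction_percent(0.16, 0.23)), 30)
  expect_equal(sf_reduction_percent(0.5, 0.5), 0)
  expect_error(sf_reduction_percent(0.5, 0), "positive")
})

test_that("run_lem_study returns tidy per-seed rows and summaries", {
  s <- run_lem_study(
    scenarios = "uniform_cytoplasm", n_gnp = 2000,
    n_points = 500, seeds = 1:2
  )
  expect_s3_class(s, "gnp_lem_study")
  expect_equal(nrow(s), 2)
  expect_true(all(s$reduction_pct >= 0))
  td <- tidy(s)
  expect_equal(td$n_seeds, 2)
  expect_equal(td$mean_reduction_pct, mean(s$reduction_pct))
  gl <- glance(s)
  expect_equal(gl$max_reduction_pct, td$mean_reduction_pct)
  expect_equal(gl$best_scenario, "uniform_cytoplasm")
})
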