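test_that("vesicle packing counts are exact ceilings", {
  expect_identical(pack_vesicles(367000, 100), 3670L)
  expect_identical(pack_vesicles(0, 100), 0L)
  expect_identical(pack_vesicles(101, 100), 2L)
  expect_error(pack_vesicles(100, 0), "at least 1")
})

test_that("distance to the nucleus surface is signed and exact", {
  expect_equal(distance_to_nucleus_surface(0, 0, 0), -4)
  expect_equal(distance_to_nucleus_surface(4, 0, 0), 0)
  expect_equal(distance_to_nucleus_surface(0, 5, 0), 1)
})

test_that("geometry constructors validate their invariants", {
  expect_error(cell_geometry(nucleus_radius_um = 6), "inside")
  expect_error(cell_geometry(semi_axis_a_um = -1), "positive")
  expect_error(vesicle_spec(occupancy = 0), "at least 1")
})

test_that("all scenarios place every GNP in the cytoplasm, outside the nucleus", {
  for (sc in c("uniform_cytoplasm", "perinuclear", "vesicle")) {
    p <- sample_gnp_positions(20000, sc, seed = 7)
    expect_equal(nrow(p), 20000)
    expect_true(all(in_cytoplasm(p)), info = sc)
  }
  expect_equal(nrow(sample_gnp_positions(0, "uniform_cytoplasm", seed = 1)), 0)
})

test_that("placements are bit-identical under the same seed", {
  for (sc in c("uniform_cytoplasm", "perinuclear", "vesicle")) {
    a <- sample_gnp_positions(5000, sc, seed = 11)
    b <- sample_gnp_positions(5000, sc, seed = 11)
    expect_identical(a$x_um, b$x_um, info = sc)
    expect_identical(a$z_um, b$z_um, info = sc)
  }
})

test_that("perinuclear placements sit closer to the nucleus than uniform ones", {
  for (seed in 1:3) {
    pu <- sample_gnp_positions(20000, "uniform_cytoplasm", seed = seed)
    pp <- sample_gnp_positions(20000, "perinuclear", seed = seed)
    du <- mean(distance_to_nucleus_surface(pu$x_um, pu$y_um, pu$z_um))
    dp <- mean(distance_to_nucleus_surface(pp$x_um, pp$y_um, pp$z_um))
    expect_lt(dp, du)
  }
})

test_that("uniform-cytoplasm octant occupancy passes a chi-squared uniformity check", {
  p <- sample_gnp_positions(100000, "uniform_cytoplasm", seed = 3)
  octant <- paste0(p$x_um > 0, p$y_um > 0, p$z_um > 0)
  fit <- suppressWarnings(stats::chisq.test(table(octant)))
  expect_gt(fit$p.value, 0.001)
})

test_that("vesicle scenario conserves occupancy and keeps vesicles apart", {
  vs <- vesicle_spec()
  p <- sample_gnp_positions(367, "vesicle", vesicle = vs, seed = 5)
  expect_equal(nrow(p), 367)
  expect_equal(max(p$vesicle_id), pack_vesicles(367, vs$occupancy))
  # last vesicle holds the remainder
  expect_equal(sum(p$vesicle_id == max(p$vesicle_id)), 67)
  expect_true(all(table(p$vesicle_id)[-max(p$vesicle_id)] == vs$occupancy))
  # GNPs lie within their vesicle radius of the per-vesicle centroid-ish
  # bound: any two GNPs in one vesicle are closer than the diameter
  one <- p[p$vesicle_id == 1, ]
  d <- as.matrix(stats::dist(one[, c("x_um", "y_um", "z_um")]))
  expect_lt(max(d), vs$diameter_nm / 1000)
})

test_that("impossible vesicle packings fail with advice rather than hanging", {
  big <- vesicle_spec(diameter_nm = 4000, occupancy = 1)
  expect_error(
    sample_gnp_positions(5000, "vesicle", vesicle = big, seed = 1,
      max_consecutive_fail = 2000
    ),
    "fewer|smaller"
  )
})

test_that("placement CSV round-trips coordinates and metadata", {
  p <- sample_gnp_positions(500, "perinuclear", seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_placement_csv(p, path)
  p2 <- read_placement_csv(path)
  expect_identical(p2$x_um, p$x_um)
  expect_identical(p2$y_um, p$y_um)
  expect_identical(p2$z_um, p$z_um)
  expect_identical(attr(p2, "scenario"), "perinuclear")
  expect_identical(attr(p2, "seed"), 9L)
})
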