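test_that("kernel energy calibration matches quadrature for several diameters and etas", {
  for (d in c(2, 10)) {
    for (eta in c(0.25, 0.5, 1)) {
      k <- make_power_law_kernel(d, kernel_calibration(eta = eta))
      target <- eta * gnp_gold_mass(d, "kg") # J per Gy
      expect_lt(abs(oracle_kernel_energy_j(k) - target) / target, 0.01)
    }
  }
  # 10 nm GNP gold mass is ~1.01e-17 g
  expect_equal(gnp_gold_mass(10), 1.01e-17, tolerance = 5e-3)
})

test_that("kernel energy scales as diameter cubed at fixed eta", {
  k10 <- make_power_law_kernel(10)
  k2 <- make_power_law_kernel(2)
  expect_equal(
    kernel_total_energy_j(k2) / kernel_total_energy_j(k10),
    1 / 125,
    tolerance = 1e-9
  )
})

test_that("generated kernels fall off monotonically and as r^-2 at exponent 2", {
  k <- make_power_law_kernel(10, n_bins = 1000)
  expect_true(all(diff(k$dose_gy_per_gy) <= 0))
  # doubling r quarters the dose, up to bin resolution
  expect_equal(kernel_dose_at(k, 2000) / kernel_dose_at(k, 1000), 0.25,
    tolerance = 0.01
  )
})

test_that("kernel lookup clamps below the first edge and is zero beyond range", {
  k <- make_power_law_kernel(10)
  last_edge <- k$bin_edges_nm[length(k$bin_edges_nm)]
  expect_identical(kernel_dose_at(k, last_edge + 1), 0)
  expect_identical(kernel_dose_at(k, last_edge), 0)
  expect_identical(kernel_dose_at(k, 0), k$dose_gy_per_gy[1])
  # a bin midpoint returns that bin's stored value
  mid <- (k$bin_edges_nm[3] + k$bin_edges_nm[4]) / 2
  expect_identical(kernel_dose_at(k, mid), k$dose_gy_per_gy[3])
  expect_error(kernel_dose_at(k, -1), "non-negative")
})

test_that("degenerate and invalid kernel parameters are rejected", {
  expect_error(make_power_law_kernel(-1), "positive")
  expect_error(make_power_law_kernel(10, n_bins = 5), "at least 10")
  expect_error(kernel_calibration(eta = -0.1), "eta")
  expect_error(kernel_calibration(exponent = 0), "exponent")
  # r_max inside the GNP
  expect_error(
    make_power_law_kernel(10, kernel_calibration(r_max_um = 0.004)),
    "exceed"
  )
})

test_that("kernel TSV write/read round-trips bit-identically", {
  k <- make_power_law_kernel(10, kernel_calibration(eta = 0.37, exponent = 2.2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_kernel_table(k, path)
  k2 <- read_kernel_table(path)
  expect_identical(k2$bin_edges_nm, k$bin_edges_nm)
  expect_identical(k2$dose_gy_per_gy, k$dose_gy_per_gy)
  expect_identical(k2$diameter_nm, k$diameter_nm)
  expect_equal(k2$calibration$eta, 0.37)
})

test_that("malformed kernel tables are rejected with the offending line", {
  k <- make_power_law_kernel(10, n_bins = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_kernel_table(k, path)

  lines <- readLines(path)
  bad <- lines
  fields <- strsplit(bad[7], "\t")[[1]] # third data row
  bad[7] <- paste(fields[2], fields[1], fields[3], sep = "\t")
  writeLines(bad, path)
  expect_error(read_kernel_table(path), "line 7")

  bad <- lines
  bad[8] <- sub("([0-9.e+-]+)$", "-1", bad[8])
  writeLines(bad, path)
  expect_error(read_kernel_table(path), "line 8")

  writeLines(lines[-2], path) # drop the eta metadata line
  expect_error(read_kernel_table(path), "eta")
})

test_that("a single-bin kernel carries the full calibration energy in one shell", {
  k <- make_power_law_kernel(10, n_bins = 10)
  edges <- k$bin_edges_nm[1:2]
  shell_kg <- (4 / 3) * pi * (edges[2]^3 - edges[1]^3) * 1e-24
  one <- structure(
    list(
      diameter_nm = 10, bin_edges_nm = edges,
      dose_gy_per_gy = kernel_total_energy_j(k) / shell_kg,
      calibration = k$calibration
    ),
    class = "radial_dose_kernel"
  )
  expect_equal(kernel_total_energy_j(one), kernel_total_energy_j(k),
    tolerance = 1e-12
  )
})
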