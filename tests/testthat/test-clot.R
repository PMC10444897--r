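test_that("Davies law gives fibrous-medium permeabilities with the right scalings", {
  # frozen hand evaluation of the law at ns = 0.05, Rf = 140 nm
  expect_equal(davies_permeability(1.4e-7, 0.05), 1.088e-13,
               tolerance = 1e-3)
  # Rf^2 scaling and monotone decrease in solid fraction
  expect_equal(davies_permeability(2.8e-7, 0.05) /
                 davies_permeability(1.4e-7, 0.05), 4, tolerance = 1e-12)
  ns <- seq(0.01, 0.5, by = 0.01)
  expect_true(all(diff(davies_permeability(1.4e-7, ns)) < 0))
  # empty voxel is the open marker, not a finite permeability
  expect_identical(davies_permeability(1.4e-7, 0), Inf)
  expect_error(davies_permeability(1.4e-7, 1), "ns")
})

test_that("bounce-back fraction maps permeability onto (0,1) with correct limits", {
  nu <- 1e-6; dt <- 2.5e-5
  # frozen dimensional-analysis value: k = 1e-13 m^2 under the standard
  # discretization -> gamma = 1/(1 + 2e-13 / 2.5e-11)
  expect_equal(gamma_from_permeability(1e-13, nu, dt), 0.99206,
               tolerance = 1e-4)
  expect_equal(gamma_from_permeability(Inf, nu, dt), 0)
  expect_equal(gamma_from_permeability(0, nu, dt), 1)
  k <- 10^seq(-14, -10, by = 0.5)
  g <- gamma_from_permeability(k, nu, dt)
  expect_true(all(diff(g) < 0))
  expect_true(all(g > 0 & g < 1))
})

test_that("fiber radius shrinks with the square root of fibrin under calibration", {
  cal <- calibrate_clot(F0 = 2, Rf0 = 1.4e-7, ns0 = 0.05)
  expect_equal(radius_from_fibrin(2, 2, cal$Rf0, cal$lden, cal$Ccal),
               1.4e-7, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(radius_from_fibrin(1, 2, cal$Rf0, cal$lden, cal$Ccal),
               1.4e-7 / sqrt(2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(radius_from_fibrin(0, 2, cal$Rf0, cal$lden, cal$Ccal),
               0, ignore_attr = TRUE)
  expect_error(radius_from_fibrin(3, 2, cal$Rf0, cal$lden, cal$Ccal),
               "F")
})

test_that("solid fraction is the cylinder cross-section times strand length", {
  expect_equal(solid_fraction(0, 8e11), 0)
  # halving the cross-section halves the solid fraction
  lden <- 0.05 / (pi * (1.4e-7)^2)    # chosen so ns = 0.05 at Rf = 140 nm
  expect_equal(lden, 8.12e11, tolerance = 1e-3)
  expect_equal(solid_fraction(1.4e-7, lden), 0.05, tolerance = 1e-12)
  expect_equal(solid_fraction(1.4e-7 / sqrt(2), lden), 0.025,
               tolerance = 1e-12)
  expect_error(solid_fraction(1e-5, 8e11), "packing")
})

test_that("calibration inverts Davies' law and round-trips the permeability", {
  cal <- calibrate_clot(F0 = 2, Rf0 = 1.4e-7, k0 = 1e-13)
  # forward evaluation closes the loop
  expect_equal(davies_permeability(cal$Rf0, cal$ns0), 1e-13,
               tolerance = 1e-6)
  expect_gt(cal$ns0, 0.045); expect_lt(cal$ns0, 0.065)
  # calibrating from ns0 instead reproduces the same state
  cal2 <- calibrate_clot(F0 = 2, Rf0 = 1.4e-7, ns0 = cal$ns0)
  expect_equal(cal2$k0, 1e-13, tolerance = 1e-6)
  expect_error(calibrate_clot(2, 1.4e-7), "exactly one")
  expect_error(calibrate_clot(2, 1.4e-7, ns0 = 0.05, k0 = 1e-13),
               "exactly one")
  expect_error(calibrate_clot(0, 1.4e-7, k0 = 1e-13), "F0")
  # permeability far outside the fibrous regime has no Davies root
  expect_error(calibrate_clot(2, 1.4e-7, k0 = 1e-2), "no solid fraction")
})

test_that("type-1 generator draws uniform fields with the stated range and mean", {
  spec <- clot_spec(F_M = 2, kind = "type1", dispersion = 100,
                    length_m = 5e-3, width_m = 5.8e-3, seed = 11)
  F <- generate_type1(spec, dx = 1e-4)
  expect_equal(dim(F), c(50L, 58L))
  expect_true(all(F >= 0 & F <= 4))
  # empirical mean within 3 standard errors of the target
  se <- (4 - 0) / sqrt(12) / sqrt(length(F))
  expect_lt(abs(mean(F) - 2), 3 * se)

  spec50 <- clot_spec(F_M = 2, kind = "type1", dispersion = 50,
                      length_m = 5e-3, width_m = 5.8e-3, seed = 12)
  F50 <- generate_type1(spec50, dx = 1e-4)
  expect_true(all(F50 >= 1 & F50 <= 3))
  se50 <- 2 / sqrt(12) / sqrt(length(F50))
  expect_lt(abs(mean(F50) - 2), 3 * se50)

  # zero dispersion degenerates to the homogeneous field
  spec0 <- clot_spec(F_M = 2, kind = "type1", dispersion = 0, seed = 3)
  expect_true(all(generate_type1(spec0, 1e-4) == 2))

  # seed contract: bit-for-bit reproducible, different seeds differ
  expect_identical(generate_type1(spec, 1e-4), generate_type1(spec, 1e-4))
  spec_b <- spec; spec_b$seed <- 99L
  expect_false(identical(generate_type1(spec, 1e-4),
                         generate_type1(spec_b, 1e-4)))
})

test_that("type-2 generator hits the target mean exactly with feasible disks", {
  spec <- clot_spec(F_M = 2, kind = "type2", F_disk = 3.5,
                    length_m = 5e-3, width_m = 5.8e-3,
                    disk_radius_m = 5e-4, seed = 21)
  F <- generate_type2(spec, dx = 1e-4)
  expect_equal(mean(F), 2, tolerance = 1e-12)
  expect_setequal(unique(as.numeric(F)), c(attr(F, "F_outer"), 3.5))
  expect_gt(attr(F, "F_outer"), 0)
  expect_lt(attr(F, "F_outer"), 2)

  # F_disk at the mean degenerates to a homogeneous clot
  spec_h <- clot_spec(F_M = 2, kind = "type2", F_disk = 2, seed = 4)
  expect_true(all(generate_type2(spec_h, 1e-4) == 2))

  # same seed -> same layout; different seed -> different layout, same mean
  expect_identical(generate_type2(spec, 1e-4), generate_type2(spec, 1e-4))
  spec_b <- spec; spec_b$seed <- 22L
  F_b <- generate_type2(spec_b, 1e-4)
  expect_false(identical(F, F_b))
  expect_equal(mean(F_b), 2, tolerance = 1e-12)

  # oversize disks leave no room for a non-negative outer concentration
  spec_bad <- clot_spec(F_M = 2, kind = "type2", F_disk = 3.9,
                        length_m = 3e-3, width_m = 3e-3,
                        n_disks = 40L, disk_radius_m = 1e-3, seed = 5)
  expect_error(generate_type2(spec_bad, 1e-4), "infeasible|whole clot")
})

test_that("fibrin-to-gamma chain is consistent and monotone", {
  units <- lb_units(1e-4, 2.5e-5, 1e-6)
  cal <- calibrate_clot(F0 = 2, Rf0 = 1.4e-7, k0 = 1e-13)
  spec <- clot_spec(F_M = 2, kind = "homogeneous", length_m = 1e-3,
                    width_m = 5e-4)
  clot <- generate_clot(spec, cal, 1e-4)
  ch <- clot_chain(clot, units)
  # homogeneous clot: uniform gamma equal to the direct mapping of k0
  g0 <- gamma_from_permeability(1e-13, units$nu, units$dt)
  expect_equal(as.numeric(ch$gamma), rep(g0, length(clot$F)))
  # round trip through the chain reproduces the calibration permeability
  expect_equal(as.numeric(ch$k), rep(1e-13, length(clot$F)),
               tolerance = 1e-6)

  # lysis monotonicity: halve fibrin everywhere -> larger k, smaller gamma
  clot2 <- clot; clot2$F <- clot$F / 2
  ch2 <- clot_chain(clot2, units)
  expect_true(all(ch2$k > ch$k))
  expect_true(all(ch2$gamma < ch$gamma))
  expect_equal(as.numeric(ch2$ns), as.numeric(ch$ns) / 2, tolerance = 1e-12)

  # fully dissolved voxel is open
  clot3 <- clot; clot3$F[1, 1] <- 0
  ch3 <- clot_chain(clot3, units)
  expect_equal(ch3$gamma[1, 1], 0)
  expect_identical(ch3$k[1, 1], Inf)
})

test_that("heterogeneous clots embed per-voxel calibration consistently", {
  units <- lb_units(1e-4, 2.5e-5, 1e-6)
  cal <- calibrate_clot(F0 = 2, Rf0 = 1.4e-7, k0 = 1e-13)
  spec <- clot_spec(F_M = 2, kind = "type1", dispersion = 75,
                    length_m = 2e-3, width_m = 1e-3, seed = 8)
  clot <- generate_clot(spec, cal, 1e-4)
  ch <- clot_chain(clot, units)
  # initial fiber radius is uniform; solid fraction tracks concentration
  expect_true(all(abs(ch$Rf[clot$F0 > 0] - 1.4e-7) < 1e-20))
  expect_equal(as.numeric(ch$ns), as.numeric(cal$ns0 * clot$F / 2),
               tolerance = 1e-12)
  # denser voxels are less permeable
  o <- order(as.numeric(clot$F))
  expect_true(all(diff(as.numeric(ch$k)[o]) <= 0))
})
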