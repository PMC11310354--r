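test_that("temporal profile follows the ramp-hold-relax protocol", {
  expect_equal(temporal_profile(0), 0)
  expect_equal(temporal_profile(3), 1)
  expect_equal(temporal_profile(8), 1)
  expect_equal(temporal_profile(9.5), (11 - 9.5) / 3)  # mid-relaxation
  expect_equal(temporal_profile(11), 0)
  expect_equal(temporal_profile(20), 0)
  expect_equal(temporal_profile(1.5), 0.5)
  expect_error(temporal_profile(-1), "non-negative")
})

test_that("prescribed strain field honours ratio and incompressibility", {
  g <- default_geometry(64, 64)
  f0 <- build_strain_field(0, g)
  expect_true(all(f0$exx == 0) && all(f0$eyy == 0) && all(f0$exy == 0))

  f <- build_strain_field(0.10, g)
  sup <- f$exx[g$band_rows[1], 1]
  deep <- f$exx[g$band_rows[2], 1]
  expect_equal(sup, 0.075)
  expect_equal(sup / deep, 0.75, tolerance = 1e-12)
  expect_equal(f$eyy[g$band_rows[2], 1], 1 / 1.10 - 1)
  # area stretch is exactly one everywhere
  expect_lt(max(abs((1 + f$exx) * (1 + f$eyy) - 1)), 1e-9)
  expect_error(build_strain_field(0.6, g), "< 0.5")
})

test_that("strain field grades smoothly and decays outside the band", {
  g <- default_geometry(64, 64)
  f <- build_strain_field(-0.08, g)
  prof <- attr(f, "profile")
  expect_equal(prof[g$band_rows[1]], -0.06)
  expect_equal(prof[g$band_rows[2]], -0.08)
  expect_equal(prof[1], 0)
  expect_equal(prof[64], 0)
  # monotone in magnitude across the band
  band <- prof[g$band_rows[1]:g$band_rows[2]]
  expect_true(all(diff(abs(band)) > 0))
})

test_that("displacement integration matches analytic solutions", {
  z <- zero_strain_field(32, 32)
  d0 <- strain_to_displacement(z)
  expect_true(all(d0$u == 0) && all(d0$v == 0))

  # uniform stretch anchored at the left edge: u(x) = eps * x
  u5 <- matrix(0.05, 32, 48)
  f <- strain_field(u5, u5 * 0, u5 * 0)
  d <- strain_to_displacement(f, anchor = c(1, 1))
  expect_equal(d$u[1, ], 0.05 * (seq_len(48) - 1), tolerance = 1e-12)
  expect_true(all(abs(d$v[1, ]) < 1e-12))
})

test_that("displacement round-trip reproduces smooth fields", {
  # uniform field: exact everywhere in the interior
  f <- strain_field(matrix(0.08, 48, 48), matrix(0, 48, 48),
                    matrix(1 / 1.08 - 1, 48, 48))
  rec <- strain_from_displacement(strain_to_displacement(f))
  i <- 2:47
  expect_lt(max(abs(rec$exx[i, i] - f$exx[i, i])), 1e-3)
  expect_lt(max(abs(rec$eyy[i, i] - f$eyy[i, i])), 1e-3)
  expect_lt(max(abs(rec$exy[i, i] - f$exy[i, i])), 1e-3)

  # generated tendon field: exact within the band interior, where the
  # stored shear is the kinematically consistent one
  g <- default_geometry(64, 64)
  ft <- build_strain_field(0.08, g)
  rect <- strain_from_displacement(strain_to_displacement(ft))
  rows <- (g$band_rows[1] + 1):(g$band_rows[2] - 1)
  cols <- 2:63
  expect_lt(max(abs(rect$exx[rows, cols] - ft$exx[rows, cols])), 1e-3)
  expect_lt(max(abs(rect$eyy[rows, cols] - ft$eyy[rows, cols])), 1e-3)
  expect_lt(max(abs(rect$exy[rows, cols] - ft$exy[rows, cols])), 1e-3)
})

test_that("integration refuses invalid pixels", {
  f <- zero_strain_field(16, 16)
  f$valid_mask[5, 5] <- FALSE
  expect_error(strain_to_displacement(f), "valid")
})
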