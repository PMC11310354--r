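test_that("bulk longitudinal strain pools the hold-phase median", {
  g <- default_geometry(16, 16)
  mk <- function(v) strain_field(matrix(v, 16, 16), matrix(0, 16, 16),
                                 matrix(0, 16, 16))
  fields <- list(mk(0.01), mk(0.04), mk(0.06), mk(0.02))
  times <- c(1, 4, 6, 10)
  expect_equal(bulk_longitudinal_strain(fields, g, times), 0.05)
  # constant field passes through
  expect_equal(bulk_longitudinal_strain(list(mk(0.05)), g, 5), 0.05)
  # mask contract: excluded pixels do not contribute
  f <- mk(0.04)
  f$exx[!g$tendon_mask] <- 99
  expect_equal(bulk_longitudinal_strain(list(f), g, 5), 0.04)
  expect_error(bulk_longitudinal_strain(fields, g, times,
                                        hold_window = c(20, 30)), "hold")
})

test_that("pooled tendon median matches a brute-force loop", {
  g <- default_geometry(12, 12)
  set.seed(8)
  fields <- lapply(1:3, function(k)
    strain_field(matrix(rnorm(144, 0.05, 0.01), 12, 12),
                 matrix(0, 12, 12), matrix(0, 12, 12)))
  pool <- c()
  for (f in fields) for (i in 1:12) for (j in 1:12)
    if (g$tendon_mask[i, j]) pool <- c(pool, f$exx[i, j])
  expect_equal(bulk_longitudinal_strain(fields, g, times = c(3, 5, 7)),
               stats::median(pool), tolerance = 1e-12)
})

test_that("force transmission and stress arithmetic", {
  expect_equal(tendon_force(0), 0)
  expect_equal(tendon_force(289.8, list(k = 0.25)), 72.45)
  expect_equal(tendon_force(100) * 2, tendon_force(200))
  expect_error(tendon_force(10, list(k = -1)), "> 0")
  expect_error(tendon_force(-5), "non-negative")
  expect_equal(stress(50, 10), 5)    # N / mm^2 = MPa
  expect_equal(stress(0, 10), 0)
  expect_error(stress(10, 0), "positive")
})

test_that("apparent modulus finds the linear region", {
  # exactly linear: slope recovered exactly
  eps <- seq(0.001, 0.02, length.out = 20)
  fit <- apparent_modulus(80 * eps, eps)
  expect_equal(fit$modulus, 80, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)

  # toe region (quadratic) followed by a linear limb of slope 120
  eps <- seq(0.001, 0.03, length.out = 30)
  toe_end <- 0.012
  sig <- ifelse(eps < toe_end,
                120 * eps^2 / (2 * toe_end),
                120 * (eps - toe_end / 2))
  fit <- apparent_modulus(sig, eps, window_fraction = 0.3)
  expect_gt(fit$modulus, 114); expect_lt(fit$modulus, 126)

  # pure noise: selected slope stays within a few standard errors of zero
  set.seed(5)
  eps <- seq(0.001, 0.02, length.out = 40)
  sig <- rnorm(40, sd = 0.05)
  fit <- apparent_modulus(sig, eps)
  # max-R2 window selection favours the strongest spurious trend, so the
  # slope is judged against its own standard error with selection slack
  expect_lt(abs(fit$modulus), 6 * fit$se)
  expect_error(apparent_modulus(sig, rep(0.01, 40)), "constant")
  expect_error(apparent_modulus(sig[1:3], eps[1:3]), "at least 5")
})

test_that("effort regression recovers exact and degenerate lines", {
  x <- c(0.1, 0.3, 0.5, 0.1, 0.3, 0.5)
  fit <- effort_regression(x, 2 * x)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  fitc <- effort_regression(x, rep(0.04, 6))
  expect_equal(fitc$slope, 0, tolerance = 1e-10)
  expect_equal(fitc$r_squared, 0)
  expect_error(effort_regression(x[1:2], x[1:2]), "at least 3")
})

test_that("effort regression covers a known slope across replicates", {
  # Monte-Carlo coverage of the 95% CI for a known slope
  hits <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    eff <- rep(c(0.1, 0.3, 0.5), each = 5)
    y <- 0.1 * eff + rnorm(15, sd = 0.005)
    fit <- effort_regression(eff, y)
    ci <- stats::confint(fit$model)["effort", ]
    if (ci[1] <= 0.1 && 0.1 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.90)
})

test_that("stress-strain records assemble and fit the loading phase", {
  times <- seq(0, 11, by = 0.5)
  prof <- temporal_profile(times)
  strain <- 0.05 * prof
  E <- 90
  sig <- E * strain
  csa <- 12
  k <- 0.25
  grip <- sig * csa / k
  rec <- stress_strain_record(times, grip, strain, csa,
                              transmission = list(k = k))
  expect_s3_class(rec, "stress_strain_record")
  expect_equal(rec$apparent_modulus, E, tolerance = 1e-8)
  expect_error(stress_strain_record(c(0, 0, 1), grip[1:3], strain[1:3], csa),
               "increase")
})
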