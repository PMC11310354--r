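test_that("spatial strain error expands the symmetric tensor", {
  z <- zero_strain_field(4, 4)
  expect_true(all(spatial_strain_error(z, z) == 0))
  p <- zero_strain_field(4, 4)
  p$exx[2, 2] <- 0.03
  e <- spatial_strain_error(p, z)
  expect_equal(e[2, 2], 0.03)
  expect_equal(sum(e > 0), 1)
  p2 <- zero_strain_field(4, 4)
  p2$exy[1, 1] <- 0.03
  expect_equal(spatial_strain_error(p2, z)[1, 1], 0.03 * sqrt(2))
})

test_that("per-frame and pooled medians follow their contracts", {
  mask <- matrix(TRUE, 2, 3)
  m1 <- matrix(0.01, 2, 3)
  m2 <- matrix(0.03, 2, 3)
  expect_equal(strain_error(m1, mask)$median, 0.01)
  expect_equal(strain_error(matrix(c(0.01, 0.02, 0.03, 0.01, 0.02, 0.03),
                                   2, 3), mask)$median, 0.02)
  # pooled median of two equal-sized frames, not median-of-medians
  expect_equal(median_strain_error(list(m1, m2), mask), 0.02)
  expect_equal(median_strain_error(list(m1), mask), 0.01)
  # masked-out extremes are ignored
  m3 <- m1; m3[1, 1] <- 99
  msk <- mask; msk[1, 1] <- FALSE
  expect_equal(strain_error(m3, msk)$median, 0.01)
  expect_error(strain_error(m1, matrix(FALSE, 2, 3)), "empty")
})

test_that("metric implementations match brute-force scalar loops", {
  for (seed in 1:3) {
    pred <- random_field(6, 5, seed = seed)
    truth <- random_field(6, 5, seed = seed + 5)
    got <- spatial_strain_error(pred, truth)
    for (i in 1:6) for (j in 1:5) {
      acc <- 0
      Ph <- matrix(c(pred$exx[i, j], pred$exy[i, j],
                     pred$exy[i, j], pred$eyy[i, j]), 2)
      Tr <- matrix(c(truth$exx[i, j], truth$exy[i, j],
                     truth$exy[i, j], truth$eyy[i, j]), 2)
      for (a in 1:2) for (b in 1:2) acc <- acc + (Ph[a, b] - Tr[a, b])^2
      expect_equal(got[i, j], sqrt(acc), tolerance = 1e-12)
    }
  }
})

test_that("median strain error is invariant to frame order", {
  mask <- matrix(TRUE, 3, 3)
  maps <- lapply(1:4, function(k) matrix(runif(9), 3, 3))
  expect_equal(median_strain_error(maps, mask),
               median_strain_error(rev(maps), mask))
})

test_that("overlap mask is the pixelwise conjunction", {
  a <- matrix(TRUE, 3, 3)
  b <- a; b[1, ] <- FALSE
  expect_identical(overlap_mask(list(a)), a)
  expect_identical(overlap_mask(list(a, b)), b)
  dis1 <- a; dis1[, 1:2] <- FALSE
  dis2 <- a; dis2[, 3] <- FALSE
  expect_error(overlap_mask(list(dis1, dis2)), "empty overlap")
})

test_that("permutation test has the documented estimator and symmetry", {
  # identical constant samples: every permuted difference ties at zero
  expect_equal(permutation_test(rep(1, 10), rep(1, 10), n_perm = 200)$p_value,
               1)
  # complete separation: only the add-one term remains
  a <- runif(30)
  b <- runif(30) + 100
  pt <- permutation_test(a, b, n_perm = 999, seed = 4)
  expect_equal(pt$p_value, 1 / 1000)
  # symmetry in the two samples
  p1 <- permutation_test(a, b, n_perm = 300, seed = 9)$p_value
  p2 <- permutation_test(b, a, n_perm = 300, seed = 9)$p_value
  expect_equal(p1, p2)
  expect_message(permutation_test(a, b, n_perm = 99), "coarse")
})

test_that("error_summary combines maps, quartiles and pooled median", {
  truth <- list(zero_strain_field(8, 8), zero_strain_field(8, 8))
  pred <- list(zero_strain_field(8, 8), zero_strain_field(8, 8))
  pred[[1]]$exx[] <- 0.01
  pred[[2]]$exx[] <- 0.03
  es <- error_summary(pred, truth)
  expect_equal(es$per_frame$median, c(0.01, 0.03))
  expect_equal(es$overall, 0.02)
  expect_true(all(es$overlap_mask))
})
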