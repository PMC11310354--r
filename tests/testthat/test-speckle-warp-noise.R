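test_that("speckle generation is seeded and textured", {
  a <- generate_speckle_image(128, 128, seed = 1)
  b <- generate_speckle_image(128, 128, seed = 1)
  c <- generate_speckle_image(128, 128, seed = 2)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_true(min(a) >= 0 && max(a) <= 1)
  expect_gt(stats::sd(a), 0.01)
  expect_error(generate_speckle_image(0, 64), "positive")
})

test_that("speckle autocorrelation length is a few pixels", {
  # band-free texture; the bright tendon band would add long-range
  # row-to-row correlation unrelated to the speckle grain
  a <- generate_speckle_image(128, 128,
                              speckle_params = list(band_gain = 0), seed = 3)
  ac <- function(lag) {
    x <- a[, seq_len(128 - lag)]; y <- a[, seq_len(128 - lag) + lag]
    stats::cor(as.numeric(x), as.numeric(y))
  }
  # correlated at 1 px, mostly decorrelated by 8 px
  expect_gt(ac(1), 0.5)
  expect_lt(ac(8), 0.4)
})

test_that("warping by zero displacement is the identity", {
  img <- generate_speckle_image(64, 64, seed = 4)
  z <- displacement_field(matrix(0, 64, 64), matrix(0, 64, 64))
  for (dir in c("forward", "backward")) {
    w <- warp_image(img, z, direction = dir)
    expect_lt(max(abs(w[3:62, 3:62] - img[3:62, 3:62])), 1e-12)
  }
})

test_that("integer translation shifts the image exactly (interior)", {
  img <- generate_speckle_image(64, 64, seed = 5)
  d <- displacement_field(matrix(2, 64, 64), matrix(0, 64, 64))
  w <- warp_image(img, d)
  # texture at column c appears at column c + 2
  expect_lt(max(abs(w[5:60, 5:60] - img[5:60, 3:58])), 1e-8)
})

test_that("warp followed by inverse warp approximately restores the image", {
  # smooth band-free texture: the sharp band edge would dominate the
  # interpolation error budget
  img <- generate_speckle_image(64, 64,
    speckle_params = list(corr_sigma = 3, band_gain = 0), seed = 6)
  f <- strain_field(matrix(0.04, 64, 64), matrix(0, 64, 64),
                    matrix(-0.03, 64, 64))
  w <- warp_image(img, strain_to_displacement(f))
  # inverse deformation: per-axis inverse stretch ratios
  finv <- strain_field(matrix(1 / 1.04 - 1, 64, 64), matrix(0, 64, 64),
                       matrix(1 / 0.97 - 1, 64, 64))
  back <- warp_image(w, strain_to_displacement(finv))
  expect_lt(max(abs(back[8:57, 8:57] - img[8:57, 8:57])), 1e-2)
})

test_that("forward warp semantics preserve the prescribed stretch", {
  # a tracked uniform 5% stretch must read 0.05, not eps/(1-eps)
  img <- generate_speckle_image(96, 96, seed = 7)
  f <- strain_field(matrix(0.05, 96, 96), matrix(0, 96, 96),
                    matrix(0, 96, 96))
  d <- strain_to_displacement(f)
  w <- warp_image(img, d)
  # the texture of column x0 + (x - x0)*1.05 in w equals column x of img
  x0 <- (96 + 1) / 2
  cols <- seq(20, 76, by = 8)
  for (x in cols) {
    xw <- x0 + (x - x0) * 1.05
    ref <- img[30:66, x]
    got <- sample_image(w, rep(xw - 1, 37), 29:65)
    expect_gt(stats::cor(ref, got), 0.98)
  }
})

test_that("noise model is seeded, ordered, and calibrated", {
  img <- matrix(0.5, 128, 128)
  expect_identical(add_noise(img, list(), seed = 1), img)  # zero strengths
  n1 <- add_noise(img, list(speckle_sd = 0.1, gauss_sd = 0.03), seed = 2)
  n2 <- add_noise(img, list(speckle_sd = 0.1, gauss_sd = 0.03), seed = 2)
  expect_identical(n1, n2)
  # law of large numbers: additive-only sd close to nominal
  na <- add_noise(img, list(gauss_sd = 0.05), seed = 3)
  expect_gt(stats::sd(na - img), 0.045)
  expect_lt(stats::sd(na - img), 0.055)
  expect_error(add_noise(img, list(gauss_sd = -1)), "non-negative")
  expect_error(add_noise(img * 4, list()), "\\[0, 1\\]")
})
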