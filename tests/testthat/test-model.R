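test_that("classifier is seed-reproducible and outputs a simplex point", {
  m1 <- build_classifier(seed = 3)
  m2 <- build_classifier(seed = 3)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, build_classifier(seed = 4)$params))

  x <- array(runif(64 * 64 * 2 * 2), c(64, 64, 2, 2))
  fwd <- strainkit:::classifier_forward(m1, x)
  expect_equal(colSums(fwd$probs), c(1, 1), tolerance = 1e-6)
  expect_true(all(fwd$probs >= 0))
})

test_that("classifier parameter count matches a hand-computed tally", {
  m <- build_classifier(depth = 2, widths = c(4, 8), input_size = c(32, 32),
                        hidden = 10, seed = 1)
  # conv1: 9*2*4 + 4; bn1: 2*4; conv2: 9*4*8 + 8; bn2: 2*8
  # flatten: (32/4)^2 * 8 = 512 -> fc1: 512*10 + 10; fc2: 10*3 + 3
  manual <- (9 * 2 * 4 + 4) + 8 + (9 * 4 * 8 + 8) + 16 +
    (512 * 10 + 10) + (10 * 3 + 3)
  expect_equal(n_parameters(m), manual)
})

test_that("regressor output matches input shape with 3 channels", {
  m <- build_regressor(seed = 5)
  x <- array(runif(64 * 48 * 2), c(64, 48, 2, 1))
  y <- strainkit:::regressor_forward(m, x)$y
  expect_equal(dim(y), c(64, 48, 3, 1))
  expect_true(all(is.finite(y)))
  # same seed, same output
  y2 <- strainkit:::regressor_forward(build_regressor(seed = 5), x)$y
  expect_identical(y, y2)
  expect_error(strainkit:::regressor_forward(m,
    array(0, c(60, 60, 2, 1))), "divisible")
})

test_that("skip connections add exactly the concatenation widths", {
  w <- c(4, 8, 16)
  with_sk <- build_regressor(widths = w, skip = TRUE, seed = 1)
  without <- build_regressor(widths = w, skip = FALSE, seed = 1)
  # each decoder conv gains 9 * width_skip rows of kernel per output channel
  extra <- sum(9 * w * w)   # dec_i: 9 * w[i] extra inputs * w[i] outputs
  expect_equal(n_parameters(with_sk) - n_parameters(without), extra)
})

test_that("untrained regressor is translation-covariant in the interior", {
  m <- build_regressor(depth = 2, widths = c(4, 8), seed = 9)
  img <- generate_speckle_image(128, 128, seed = 2)
  x1 <- array(c(img, img), c(128, 128, 2, 1))
  sh <- 8L  # a multiple of the pooling period
  imgs <- rbind(img[(sh + 1):128, ], img[rep(1, sh), ])  # shift rows up
  x2 <- array(c(imgs, imgs), c(128, 128, 2, 1))
  y1 <- strainkit:::regressor_forward(m, x1)$y
  y2 <- strainkit:::regressor_forward(m, x2)$y
  i <- 48:64  # rows whose receptive cones avoid every border
  expect_lt(max(abs(y2[i, 30:100, 1, 1] - y1[i + sh, 30:100, 1, 1])), 1e-8)
})

test_that("classify_pair breaks ties toward the lowest class index", {
  probs <- c(0.4, 0.4, 0.2)
  idx <- which(probs == max(probs))[1] - 1L
  expect_equal(deformation_class(idx)$label, "tension")
  expect_equal(deformation_class(0)$label, "tension")
  expect_equal(deformation_class("rigid")$index, 2L)
  expect_error(deformation_class(5), "0, 1 or 2")
})

test_that("checkpoints round-trip", {
  m <- list(classifier = build_classifier(depth = 2, widths = c(2, 4),
                                          input_size = c(16, 16), seed = 1))
  path <- file.path(tempdir(), "ckpt-test")
  unlink(path, recursive = TRUE)
  save_checkpoint(m, path)
  expect_error(save_checkpoint(m, path), "overwrite")
  back <- load_checkpoint(path)
  expect_identical(back$classifier$params, m$classifier$params)
  unlink(path, recursive = TRUE)
})
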