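test_that("cross-entropy matches closed forms", {
  expect_equal(cross_entropy(c(1, 0, 0), 0), 0)
  expect_equal(cross_entropy(rep(1, 3) / 3, 1), log(3))
  expect_equal(cross_entropy(c(0.5, 0.25, 0.25), 0), log(2))
  # clipping keeps zero-probability labels finite
  expect_equal(cross_entropy(c(0, 1, 0), 0), -log(1e-12))
  expect_error(cross_entropy(c(0.5, 0.5), 0), "length 3")
  expect_error(cross_entropy(c(0.9, 0.4, -0.3), 0), "simplex")
})

test_that("mean l2 loss counts the shear component twice", {
  z <- zero_strain_field(1, 1)
  p_xx <- strain_field(matrix(0.1), matrix(0), matrix(0))
  expect_equal(mean_l2_loss(p_xx, z), 0.01)
  p_xy <- strain_field(matrix(0), matrix(0.1), matrix(0))
  expect_equal(mean_l2_loss(p_xy, z), 0.02)   # ij = 12 and ij = 21
  expect_equal(mean_l2_loss(z, z), 0)
})

test_that("losses agree with brute-force scalar loops", {
  # independent oracle: explicit loops over examples, pixels and the full
  # 2x2 tensor with e_yx = e_xy
  for (seed in 1:3) {
    pred <- list(random_field(5, 4, seed = seed),
                 random_field(5, 4, seed = seed + 10))
    truth <- list(random_field(5, 4, seed = seed + 20),
                  random_field(5, 4, seed = seed + 30))
    acc <- 0
    for (n in 1:2) for (i in 1:5) for (j in 1:4) {
      Ph <- matrix(c(pred[[n]]$exx[i, j], pred[[n]]$exy[i, j],
                     pred[[n]]$exy[i, j], pred[[n]]$eyy[i, j]), 2)
      Tr <- matrix(c(truth[[n]]$exx[i, j], truth[[n]]$exy[i, j],
                     truth[[n]]$exy[i, j], truth[[n]]$eyy[i, j]), 2)
      for (a in 1:2) for (b in 1:2) acc <- acc + (Ph[a, b] - Tr[a, b])^2
    }
    expect_equal(mean_l2_loss(pred, truth), acc / (2 * 20),
                 tolerance = 1e-10)
  }
  probs <- c(0.2, 0.5, 0.3)
  y <- c(0, 1, 0)
  expect_equal(cross_entropy(probs, 1),
               -sum(y * log(probs)), tolerance = 1e-12)
})

test_that("network gradients match numerical differentiation", {
  set.seed(31)
  m <- build_regressor(depth = 2, widths = c(3, 4), seed = 5)
  x <- array(runif(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  tb <- array(rnorm(8 * 8 * 3 * 2, sd = 0.05), c(8, 8, 3, 2))
  wch <- array(rep(c(1, 2, 1), each = 64), c(8, 8, 3, 2))
  lossfun <- function(params) {
    m2 <- m; m2$params <- params
    fwd <- strainkit:::regressor_forward(m2, x, training = TRUE)
    sum(wch * (fwd$y - tb)^2) / (2 * 64)
  }
  fwd <- strainkit:::regressor_forward(m, x, training = TRUE)
  g <- strainkit:::regressor_backward(m, fwd, 2 * wch * (fwd$y - tb) / 128)
  for (nm in c("enc1", "dec1", "bott", "head", "ebn2")) {
    for (pn in intersect(names(m$params[[nm]]),
                         c("w", "b", "gamma", "beta"))) {
      p0 <- m$params[[nm]][[pn]]
      i <- sample(length(p0), 1)
      h <- 1e-6
      pp <- m$params
      pp[[nm]][[pn]][i] <- p0[i] + h; lp <- lossfun(pp)
      pp[[nm]][[pn]][i] <- p0[i] - h; lm <- lossfun(pp)
      num <- (lp - lm) / (2 * h)
      expect_equal(g[[nm]][[pn]][i], num, tolerance = 1e-3,
                   label = paste("grad", nm, pn))
    }
  }
})

test_that("stratified split is exact, disjoint and reproducible", {
  fake <- function(lbl) structure(list(cls = deformation_class(lbl)),
                                  class = "synthetic_sample")
  samples <- c(replicate(1250, fake("tension"), simplify = FALSE),
               replicate(1250, fake("compression"), simplify = FALSE),
               replicate(1250, fake("rigid"), simplify = FALSE))
  sp <- split_dataset(samples, 0.2, seed = 3)
  expect_length(sp$train, 3000)
  expect_length(sp$val, 750)
  sp2 <- split_dataset(samples, 0.2, seed = 3)
  expect_identical(lapply(sp$train, function(s) s$cls$label),
                   lapply(sp2$train, function(s) s$cls$label))
  # per-class stratification
  ctr <- table(vapply(sp$train, function(s) s$cls$label, character(1)))
  expect_true(all(ctr == 1000))
  expect_error(split_dataset(samples[1:4], 0.2), "at least 5")
  expect_error(split_dataset(samples, 1.2), "\\(0, 1\\)")
})

test_that("a tiny regressor learns a single noise-free deformation mode", {
  # learnability floor: validation loss far below the truth variance
  samples <- generate_training_set(
    60, class_mix = c(1, 0, 0),
    noise_ranges = list(speckle_sd = c(0, 0), gauss_sd = c(0, 0),
                        gain = c(1, 1), offset = c(0, 0)),
    seed = 51)
  cfg <- training_config("tiny", epochs = 25L, seed = 51)
  sp <- split_dataset(samples, 0.25, seed = 2)
  reg <- strainkit:::train_regressor(sp$train, sp$val, cfg, "tension", 31)
  truth_var <- mean(vapply(sp$val, function(s)
    stats::var(as.numeric(s$truth$exx)) + stats::var(as.numeric(s$truth$eyy)),
    numeric(1)))
  expect_lt(reg$val_loss, truth_var / 10)
  # loss improved from the first epoch to the best epoch
  expect_lt(min(reg$log$val_loss), reg$log$val_loss[1])
})
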