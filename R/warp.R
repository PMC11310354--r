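#' Warp an image by a displacement field
#'
#' Resamples `image` under the deformation described by `disp` with
#' sub-pixel interpolation; out-of-domain samples are edge replicated.
#'
#' Two displacement semantics are supported.  `direction = "forward"`
#' (default) treats `(u, v)` as material (Lagrangian) displacements: the
#' texture at reference pixel X appears at X + U(X) in the output, so tracking
#' the output against the input recovers exactly the prescribed deformation.
#' The required inverse mapping is computed per pixel by damped fixed-point
#' iteration, valid while the displacement gradient stays below 1.
#' `direction = "backward"` is the classical pull-back
#' `out(x) = image(x - u(x))`, which differs from the forward semantics at
#' second order in strain.
#'
#' @param image numeric matrix.
#' @param disp a `displacement_field` of the same shape (pixels).
#' @param interpolation `"bicubic"` (default) or `"bilinear"`.
#' @param direction `"forward"` or `"backward"` (see Details).
#' @return Warped numeric matrix, same shape, clipped to the input range.
#' @export
warp_image <- function(image, disp, interpolation = c("bicubic", "bilinear"),
                       direction = c("forward", "backward")) {
  interpolation <- match.arg(interpolation)
  direction <- match.arg(direction)
  if (!identical(dim(image), dim(disp$u)))
    stop("image and displacement field shapes differ")
  out <- if (direction == "backward")
    .warp_backward_cpp(image, disp$u, disp$v, interpolation)
  else
    .warp_forward_cpp(image, disp$u, disp$v, interpolation, 60L, 1e-8)
  # bicubic can overshoot; keep intensities inside the input range
  pmin(pmax(out, min(image)), max(image))
}

#' Sample an image at sub-pixel positions
#'
#' @param image numeric matrix.
#' @param x,y 0-based sample coordinates (x = column, y = row), any shape.
#' @param method `"bicubic"` or `"bilinear"`.
#' @return Numeric vector of sampled intensities (edge-replicated outside).
#' @export
sample_image <- function(image, x, y, method = c("bicubic", "bilinear")) {
  method <- match.arg(method)
  .sample_image(image, as.numeric(x), as.numeric(y), method)
}

#' Add ultrasound-like noise to an image
#'
#' Applies, in order: multiplicative speckle-like noise (pixelwise
#' gamma-distributed factor with unit mean and standard deviation
#' `speckle_sd`), additive Gaussian noise of standard deviation `gauss_sd`,
#' and a global gain/offset jitter; the result is clipped to \[0, 1\].
#'
#' @param image numeric matrix with values in \[0, 1\].
#' @param noise_params list with `speckle_sd` (default 0), `gauss_sd`
#'   (default 0), `gain` (default 1) and `offset` (default 0).
#' @param seed integer seed; the output is reproducible given the seed.
#' @return Noisy numeric matrix in \[0, 1\].
#' @export
add_noise <- function(image, noise_params = list(), seed = 1L) {
  p <- modifyList(list(speckle_sd = 0, gauss_sd = 0, gain = 1, offset = 0),
                  noise_params)
  if (p$speckle_sd < 0 || p$gauss_sd < 0)
    stop("noise standard deviations must be non-negative")
  if (min(image) < 0 || max(image) > 1)
    stop("image intensities must lie in [0, 1]")
  with_seed(seed, {
    out <- image
    if (p$speckle_sd > 0) {
      shape <- 1 / p$speckle_sd^2   # unit-mean gamma, sd = speckle_sd
      out <- out * matrix(rgamma(length(out), shape = shape, rate = shape),
                          nrow(out), ncol(out))
    }
    if (p$gauss_sd > 0)
      out <- out + matrix(rnorm(length(out), sd = p$gauss_sd),
                          nrow(out), ncol(out))
    out <- p$gain * out + p$offset
    pmin(pmax(out, 0), 1)
  })
}
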