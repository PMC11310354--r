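#' Generate a procedural speckle image with a tendon-like band
#'
#' Produces a grayscale substrate emulating B-mode ultrasound texture:
#' spatially correlated speckle (Gaussian white noise smoothed to an
#' autocorrelation length of a few pixels) overlaid with a brighter
#' horizontal band where the tendon sits.  Used as the undeformed frame of
#' every synthetic sample.
#'
#' @param height,width image size in pixels (each >= 32).
#' @param speckle_params list with elements `corr_sigma` (Gaussian smoothing
#'   sd in px, controls speckle grain, default 1.2), `band` (band row limits
#'   as fractions of height, default `c(0.30, 0.70)`), `band_gain` (brightness
#'   added inside the band, default 0.25), `edge_soft` (softening of the band
#'   edge in px, default 2).
#' @param seed integer seed; the image is a pure function of
#'   `(height, width, speckle_params, seed)`.
#' @return Numeric matrix in \[0, 1\].
#' @export
generate_speckle_image <- function(height, width, speckle_params = list(),
                                   seed = 1L) {
  if (height <= 0 || width <= 0) stop("image dimensions must be positive")
  if (height < 32 || width < 32) stop("image must be at least 32x32 px")
  p <- modifyList(list(corr_sigma = 1.2, band = c(0.30, 0.70),
                       band_gain = 0.25, edge_soft = 2), speckle_params)
  with_seed(seed, {
    z <- matrix(rnorm(height * width), height, width)
    z <- gauss_smooth(z, p$corr_sigma)
    # robust rescale of the smoothed field to [0, 1]
    q <- quantile(z, c(0.01, 0.99), names = FALSE)
    z <- pmin(pmax((z - q[1]) / (q[2] - q[1]), 0), 1)
    img <- 0.15 + 0.55 * z
    # brighter tendon band with softened edges
    r0 <- p$band[1] * height
    r1 <- p$band[2] * height
    rows <- seq_len(height)
    w <- smoothstep((rows - r0) / p$edge_soft + 0.5) *
      (1 - smoothstep((rows - r1) / p$edge_soft + 0.5))
    img <- img + p$band_gain * matrix(w, height, width)
    pmin(pmax(img, 0), 1)
  })
}

# Separable Gaussian smoothing with edge renormalisation, via banded
# Toeplitz matrices (images here are small).
#' @noRd
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  smat <- function(n) {
    m <- matrix(0, n, n)
    for (d in seq(-r, r)) {
      idx <- seq_len(n - abs(d))
      if (d >= 0) m[cbind(idx, idx + d)] <- k[d + r + 1]
      else m[cbind(idx - d, idx)] <- k[d + r + 1]
    }
    m / rowSums(m)
  }
  smat(nrow(x)) %*% x %*% t(smat(ncol(x)))
}
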