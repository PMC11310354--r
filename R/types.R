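#' Ordered grayscale image sequence
#'
#' Container for the frames \eqn{(I_t)_{t=1}^{T}} of an ultrasound-like
#' recording, together with the physical pixel spacing and frame interval.
#'
#' @param frames list of numeric matrices (rows = depth, cols = longitudinal),
#'   all of identical size, intensities in \[0, 1\].
#' @param pixel_spacing isotropic pixel size in mm/px.
#' @param frame_interval time between consecutive frames in seconds.
#' @return An object of class `image_sequence`.
#' @export
image_sequence <- function(frames, pixel_spacing = 0.05, frame_interval = 1) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("`frames` must be a list of at least two matrices (T >= 2)")
  d <- dim(frames[[1L]])
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!is.matrix(f) || !identical(dim(f), d))
      stop(sprintf("frame %d does not match the %dx%d shape of frame 1",
                   k, d[1], d[2]))
    if (!all(is.finite(f)) || min(f) < 0 || max(f) > 1)
      stop(sprintf("frame %d has intensities outside [0, 1] or non-finite", k))
  }
  structure(list(frames = frames, pixel_spacing = pixel_spacing,
                 frame_interval = frame_interval),
            class = "image_sequence")
}

#' @export
length.image_sequence <- function(x) length(x$frames)

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<image_sequence> %d frames of %dx%d px, %.3g mm/px, dt = %.3g s\n",
              length(x$frames), d[1], d[2], x$pixel_spacing, x$frame_interval))
  invisible(x)
}

#' Tendon geometry within the image
#'
#' Describes where the tendon band sits in the image and how strain is graded
#' across its thickness: the superficial (shallow) edge carries
#' `superficial_ratio` times the strain of the deep edge.
#'
#' @param tendon_mask logical matrix marking tendon pixels (a horizontal band).
#' @param superficial_ratio ratio of superficial-edge to deep-edge
#'   longitudinal strain (default 0.75).
#' @param depth_axis,long_axis axis conventions; rows are depth (superficial
#'   at the top) and columns are longitudinal throughout the package.
#' @return An object of class `tendon_geometry`.
#' @export
tendon_geometry <- function(tendon_mask, superficial_ratio = 0.75,
                            depth_axis = "rows", long_axis = "cols") {
  if (!is.matrix(tendon_mask) || !is.logical(tendon_mask))
    stop("`tendon_mask` must be a logical matrix")
  if (!any(tendon_mask)) stop("`tendon_mask` must be non-empty")
  if (superficial_ratio <= 0 || superficial_ratio > 1)
    stop("`superficial_ratio` must be in (0, 1]")
  rows <- which(apply(tendon_mask, 1, any))
  if (!identical(rows, seq(min(rows), max(rows))))
    stop("`tendon_mask` must be a contiguous band of rows")
  structure(list(tendon_mask = tendon_mask,
                 superficial_ratio = superficial_ratio,
                 depth_axis = depth_axis, long_axis = long_axis,
                 band_rows = c(min(rows), max(rows))),
            class = "tendon_geometry")
}

#' Default tendon geometry for a given image size
#'
#' A horizontal tendon band spanning the full width and the central 40% of
#' image depth, with the standard 0.75 superficial/deep strain ratio.
#'
#' @param height,width image size in pixels.
#' @param band limits of the band as fractions of image height.
#' @param superficial_ratio see [tendon_geometry()].
#' @return A `tendon_geometry`.
#' @export
default_geometry <- function(height, width, band = c(0.30, 0.70),
                             superficial_ratio = 0.75) {
  mask <- matrix(FALSE, height, width)
  r0 <- max(1L, round(band[1] * height))
  r1 <- min(height, round(band[2] * height))
  mask[r0:r1, ] <- TRUE
  tendon_geometry(mask, superficial_ratio = superficial_ratio)
}

#' Per-pixel 2D strain tensor field
#'
#' Holds the three independent components of the symmetric strain tensor
#' (\eqn{\epsilon_{xx}} longitudinal, \eqn{\epsilon_{xy}} shear,
#' \eqn{\epsilon_{yy}} transverse) plus a validity mask.
#'
#' @param exx,exy,eyy numeric matrices of equal size.
#' @param valid_mask logical matrix; values must be finite wherever it is TRUE.
#' @return An object of class `strain_field`.
#' @export
strain_field <- function(exx, exy, eyy, valid_mask = NULL) {
  d <- dim(exx)
  if (!identical(dim(exy), d) || !identical(dim(eyy), d))
    stop("exx, exy, eyy must share one shape")
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, d[1], d[2])
  if (!identical(dim(valid_mask), d)) stop("valid_mask shape mismatch")
  ok <- is.finite(exx) & is.finite(exy) & is.finite(eyy)
  if (!all(ok[valid_mask])) stop("non-finite strain inside valid_mask")
  structure(list(exx = exx, exy = exy, eyy = eyy, valid_mask = valid_mask),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  d <- dim(x$exx)
  cat(sprintf(
    "<strain_field> %dx%d px, %.1f%% valid, median exx = %.4g\n",
    d[1], d[2], 100 * mean(x$valid_mask),
    stats::median(x$exx[x$valid_mask])))
  invisible(x)
}

#' Zero strain field
#' @param height,width size in pixels.
#' @return A `strain_field` of zeros, fully valid.
#' @export
zero_strain_field <- function(height, width) {
  z <- matrix(0, height, width)
  strain_field(z, z, z)
}

#' Pixel displacement field
#'
#' @param u,v numeric matrices: longitudinal (x) and depth (y) displacement in
#'   pixels.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(u, v) {
  if (!identical(dim(u), dim(v))) stop("u and v must share one shape")
  if (!all(is.finite(u)) || !all(is.finite(v)))
    stop("displacements must be finite")
  structure(list(u = u, v = v), class = "displacement_field")
}

#' Deformation class labels in canonical order
#'
#' Fixed order: index 0 = tension, 1 = compression, 2 = rigid-body motion.
#' @return Character vector of the three class labels.
#' @export
deformation_classes <- function() c("tension", "compression", "rigid")

#' Deformation class label
#'
#' @param label one of `"tension"`, `"compression"`, `"rigid"`, or an index
#'   0/1/2 in that order.
#' @return An object of class `deformation_class` with fields `label`, `index`.
#' @export
deformation_class <- function(label) {
  lv <- deformation_classes()
  if (is.numeric(label)) {
    idx <- as.integer(label)
    if (idx < 0L || idx > 2L) stop("class index must be 0, 1 or 2")
    label <- lv[idx + 1L]
  }
  label <- match.arg(label, lv)
  structure(list(label = label, index = match(label, lv) - 1L),
            class = "deformation_class")
}
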