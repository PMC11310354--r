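#' Temporal loading profile of a contraction-hold-relaxation trial
#'
#' Piecewise-linear activation in \[0, 1\]: ramps up over `ramp` seconds,
#' holds at 1 for `hold` seconds, relaxes back to 0 over `relax` seconds, and
#' stays at 0 afterwards.  Defaults follow the 3 s / 5 s / 3 s protocol.
#'
#' @param t time(s) in seconds, vectorised, all >= 0.
#' @param protocol named numeric vector `c(ramp = , hold = , relax = )`.
#' @return Numeric vector of activations in \[0, 1\].
#' @export
temporal_profile <- function(t, protocol = c(ramp = 3, hold = 5, relax = 3)) {
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be non-negative")
  ramp <- protocol[["ramp"]]; hold <- protocol[["hold"]]
  relax <- protocol[["relax"]]
  out <- numeric(length(t))
  out[t <= ramp] <- t[t <= ramp] / ramp
  out[t > ramp & t <= ramp + hold] <- 1
  i <- t > ramp + hold & t < ramp + hold + relax
  out[i] <- (ramp + hold + relax - t[i]) / relax
  out
}

#' Build the prescribed tendon strain field
#'
#' Constructs the ground-truth strain field for a given deep-layer
#' longitudinal strain.  Longitudinal strain \eqn{\epsilon_{xx}} grades
#' linearly across the tendon thickness from `superficial_ratio * eps_deep`
#' at the superficial edge to `eps_deep` at the deep edge, and decays
#' smoothly (C1 smoothstep) to zero over a margin outside the band.  The
#' transverse strain enforces in-plane incompressibility,
#' \eqn{\epsilon_{yy} = 1/(1+\epsilon_{xx}) - 1}, so the area stretch
#' \eqn{(1+\epsilon_{xx})(1+\epsilon_{yy})} is exactly 1 everywhere.  The
#' shear component is the one kinematically consistent with the displacement
#' construction used to warp images (see
#' [strain_to_displacement()]): \eqn{\epsilon_{xy} = (x - x_0)\,
#' \phi'(y) / 2} where \eqn{\phi} is the depth profile of
#' \eqn{\epsilon_{xx}} and \eqn{x_0} the anchor column.  Inside the tendon
#' this shear is near zero (the depth gradient is shallow); in the decay
#' margin it forms the shear band expected where a stretching tendon slides
#' past stationary surrounding tissue.
#'
#' @param eps_deep deep-edge longitudinal strain, |eps_deep| < 0.5.
#' @param geometry a [tendon_geometry()].
#' @param margin_frac width of the decay margin outside the band, as a
#'   fraction of image height (default 0.15).
#' @param anchor_col column (1-based) held fixed by the deformation; default
#'   image centre.
#' @return A `strain_field` valid everywhere, with attributes `profile` and
#'   `profile_deriv` (the depth profile of \eqn{\epsilon_{xx}} and its
#'   analytic derivative, per row).
#' @export
build_strain_field <- function(eps_deep, geometry,
                               margin_frac = 0.15, anchor_col = NULL) {
  stopifnot_scalar(eps_deep, "eps_deep")
  if (abs(eps_deep) >= 0.5) stop("|eps_deep| must be < 0.5")
  H <- nrow(geometry$tendon_mask); W <- ncol(geometry$tendon_mask)
  if (is.null(anchor_col)) anchor_col <- (W + 1) / 2
  rt <- geometry$band_rows[1]; rb <- geometry$band_rows[2]
  r <- geometry$superficial_ratio
  m <- max(2, margin_frac * H)

  y <- seq_len(H)
  phi <- numeric(H); dphi <- numeric(H)
  band <- y >= rt & y <= rb
  phi[band] <- eps_deep * (r + (1 - r) * (y[band] - rt) / (rb - rt))
  dphi[band] <- eps_deep * (1 - r) / (rb - rt)
  above <- y < rt & y > rt - m
  s <- (rt - y[above]) / m
  phi[above] <- r * eps_deep * (1 - smoothstep(s))
  dphi[above] <- r * eps_deep * smoothstep_deriv(s) / m
  below <- y > rb & y < rb + m
  s <- (y[below] - rb) / m
  phi[below] <- eps_deep * (1 - smoothstep(s))
  dphi[below] <- -eps_deep * smoothstep_deriv(s) / m

  exx <- matrix(phi, H, W)
  eyy <- 1 / (1 + exx) - 1
  exy <- outer(dphi / 2, seq_len(W) - anchor_col)
  out <- strain_field(exx, exy, eyy)
  attr(out, "profile") <- phi
  attr(out, "profile_deriv") <- dphi
  attr(out, "anchor_col") <- anchor_col
  out
}

#' Integrate a strain field into a displacement field
#'
#' Longitudinal displacement `u` is the cumulative trapezoidal integral of
#' \eqn{\epsilon_{xx}} along each row from the anchor column; depth
#' displacement `v` integrates \eqn{\epsilon_{yy}} along each column from the
#' anchor row.  For fields whose \eqn{\epsilon_{xx}} is constant along x and
#' \eqn{\epsilon_{yy}} constant along y this reproduces the prescribed
#' diagonal strain exactly (up to quadrature error), and its symmetric
#' gradient carries the shear \eqn{\epsilon_{xy} = \partial u/\partial y / 2}
#' stored by [build_strain_field()].
#'
#' @param field a `strain_field`, valid everywhere.
#' @param anchor `c(row, col)` pixel (1-based) with zero displacement;
#'   default image centre.
#' @return A `displacement_field` (pixels).
#' @export
strain_to_displacement <- function(field, anchor = NULL) {
  if (!all(field$valid_mask))
    stop("field must be valid everywhere for integration")
  H <- nrow(field$exx); W <- ncol(field$exx)
  if (is.null(anchor)) anchor <- c((H + 1) %/% 2, round((W + 1) / 2))
  ar <- anchor[1]; ac <- anchor[2]
  u <- t(apply(field$exx, 1, cumtrapz_anchored, anchor = ac))
  v <- apply(field$eyy, 2, cumtrapz_anchored, anchor = ar)
  displacement_field(u, v)
}

#' Numerical strain of a displacement field
#'
#' Central-difference symmetric gradient
#' \eqn{\epsilon = (\nabla u + \nabla u^T)/2} of a pixel displacement field;
#' one-sided differences at the image border.
#'
#' @param disp a `displacement_field`.
#' @return A `strain_field` valid everywhere.
#' @export
strain_from_displacement <- function(disp) {
  ux <- grad_x(disp$u); uy <- grad_y(disp$u)
  vx <- grad_x(disp$v); vy <- grad_y(disp$v)
  strain_field(ux, (uy + vx) / 2, vy)
}

# gradient along columns (x) / rows (y), central differences inside,
# one-sided at the border
#' @noRd
grad_x <- function(a) {
  n <- ncol(a)
  g <- a
  g[, 2:(n - 1)] <- (a[, 3:n] - a[, 1:(n - 2)]) / 2
  g[, 1] <- a[, 2] - a[, 1]
  g[, n] <- a[, n] - a[, n - 1]
  g
}

#' @noRd
grad_y <- function(a) t(grad_x(t(a)))
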