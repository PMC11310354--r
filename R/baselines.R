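# Classical texture-correlation baselines: subset-based DIC (displacement
# first, strain by differentiating the displacement grid) and DDE (the
# affine deformation gradient estimated directly per subset).  Both share
# the integer NCC search and the Gauss-Newton affine refinement with a
# linear (affine) shape function.

#' Subset grid for DIC/DDE tracking
#'
#' @param image_dim `c(H, W)` of the frames.
#' @param subset_size odd subset side length in px (>= 11).
#' @param step grid spacing between subset centres in px.
#' @param search_radius integer-search radius in px.
#' @param corr_threshold minimum final normalised cross-correlation for a
#'   subset to be kept.
#' @param max_iter,tol Gauss-Newton iteration cap and convergence tolerance
#'   (translation update, px).
#' @return A `subset_grid` with centre coordinates (1-based rows/cols).
#' @export
subset_grid <- function(image_dim, subset_size = 21L, step = 8L,
                        search_radius = 8L, corr_threshold = 0.5,
                        max_iter = 50L, tol = 1e-4) {
  if (subset_size < 11 || subset_size %% 2 == 0)
    stop("`subset_size` must be odd and >= 11")
  if (step < 1) stop("`step` must be >= 1")
  half <- (subset_size - 1L) %/% 2L
  margin <- half + search_radius + 2L
  if (2L * margin + 1L > min(image_dim))
    stop("image too small for this subset size and search radius")
  rows <- seq(margin + 1L, image_dim[1] - margin, by = step)
  cols <- seq(margin + 1L, image_dim[2] - margin, by = step)
  structure(list(subset_size = subset_size, half = half, step = step,
                 search_radius = search_radius,
                 corr_threshold = corr_threshold,
                 max_iter = max_iter, tol = tol,
                 rows = rows, cols = cols, image_dim = image_dim),
            class = "subset_grid")
}

#' @noRd
ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a * a) * sum(b * b))
  if (den <= 0) return(NA_real_)
  sum(a * b) / den
}

# Integer-pixel NCC search for one subset centred at (cy, cx), 1-based.
#' @noRd
integer_search <- function(frame_a, frame_b, cy, cx, half, radius) {
  ref <- frame_a[(cy - half):(cy + half), (cx - half):(cx + half)]
  if (stats::sd(ref) < 1e-12) return(NULL)   # textureless subset
  best <- c(0, 0); best_c <- -Inf
  for (dy in -radius:radius)
    for (dx in -radius:radius) {
      win <- frame_b[(cy + dy - half):(cy + dy + half),
                     (cx + dx - half):(cx + dx + half)]
      cc <- ncc(ref, win)
      if (!is.na(cc) && cc > best_c) { best_c <- cc; best <- c(dx, dy) }
    }
  list(ref = ref, u = best[1], v = best[2], corr = best_c)
}

# Gauss-Newton refinement of a 6-parameter affine (linear shape function)
# warp minimising the zero-mean SSD of interpolated intensities.
# p = (u, v, a11, a12, a21, a22); warped sample position for subset-local
# offsets (dx, dy):  x = cx + u + (1+a11) dx + a12 dy,
#                    y = cy + v + a21 dx + (1+a22) dy   (0-based coords).
#' @noRd
gn_refine <- function(frame_b, gx, gy, ref, cy0, cx0, u0, v0, half,
                      max_iter, tol) {
  off <- seq(-half, half)
  dxm <- matrix(off, length(off), length(off), byrow = TRUE)
  dym <- matrix(off, length(off), length(off))
  dxv <- as.numeric(dxm); dyv <- as.numeric(dym)
  refc <- as.numeric(ref) - mean(ref)
  p <- c(u0, v0, 0, 0, 0, 0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    xs <- cx0 + p[1] + (1 + p[3]) * dxv + p[4] * dyv
    ys <- cy0 + p[2] + p[5] * dxv + (1 + p[6]) * dyv
    ib <- .sample_image(frame_b, xs, ys, "bicubic")
    gxs <- .sample_image(gx, xs, ys, "bilinear")
    gys <- .sample_image(gy, xs, ys, "bilinear")
    e <- (ib - mean(ib)) - refc
    J <- cbind(gxs, gys, gxs * dxv, gxs * dyv, gys * dxv, gys * dyv)
    H <- crossprod(J)
    g <- crossprod(J, e)
    dp <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(dp)) break
    p <- p + as.numeric(dp)
    if (abs(dp[1]) + abs(dp[2]) < tol) { converged <- TRUE; break }
  }
  xs <- cx0 + p[1] + (1 + p[3]) * dxv + p[4] * dyv
  ys <- cy0 + p[2] + p[5] * dxv + (1 + p[6]) * dyv
  ib <- .sample_image(frame_b, xs, ys, "bicubic")
  list(p = p, corr = ncc(ib, as.numeric(ref)), converged = converged)
}

#' @noRd
track_subsets <- function(frame_a, frame_b, grid) {
  if (!identical(dim(frame_a), dim(frame_b))) stop("frame shapes differ")
  gx <- grad_x(frame_b); gy <- grad_y(frame_b)
  nr <- length(grid$rows); nc <- length(grid$cols)
  res <- array(NA_real_, c(nr, nc, 8))   # u v a11 a12 a21 a22 corr conv
  for (i in seq_len(nr))
    for (j in seq_len(nc)) {
      cy <- grid$rows[i]; cx <- grid$cols[j]
      ints <- integer_search(frame_a, frame_b, cy, cx, grid$half,
                             grid$search_radius)
      if (is.null(ints)) next
      gn <- gn_refine(frame_b, gx, gy, ints$ref, cy - 1, cx - 1,
                      ints$u, ints$v, grid$half, grid$max_iter, grid$tol)
      res[i, j, ] <- c(gn$p, gn$corr, as.numeric(gn$converged))
    }
  res
}

# bilinear interpolation from the centre grid to the full pixel grid;
# NA centres poison their surrounding cells, shrinking the valid region.
#' @noRd
grid_to_dense <- function(rows, cols, V, H, W) {
  out <- matrix(NA_real_, H, W)
  rr <- rows[1]:rows[length(rows)]
  cc <- cols[1]:cols[length(cols)]
  # interpolate along columns of the centre grid first, then along rows
  lin <- function(x, y, xout) {
    ok <- is.finite(y)
    if (sum(ok) < 2) return(rep(NA_real_, length(xout)))
    out <- approx(x[ok], y[ok], xout = xout)$y
    # do not extrapolate across removed (invalid) centres
    out[xout < min(x[ok]) | xout > max(x[ok])] <- NA_real_
    bad <- x[!ok]
    if (length(bad))
      for (b in bad) out[abs(xout - b) < diff(x[1:2])] <- NA_real_
    out
  }
  tmp <- matrix(NA_real_, length(rr), length(cols))
  for (j in seq_along(cols))
    tmp[, j] <- lin(rows, V[, j], rr)
  dense <- matrix(NA_real_, length(rr), length(cc))
  for (i in seq_along(rr))
    dense[i, ] <- lin(cols, tmp[i, ], cc)
  out[rr, cc] <- dense
  out
}

#' @noRd
#' @importFrom stats approx
results_to_field <- function(res, grid, comp_fun) {
  nr <- dim(res)[1]; nc <- dim(res)[2]
  valid <- is.finite(res[, , 7]) & res[, , 7] >= grid$corr_threshold &
    res[, , 8] > 0
  comps <- comp_fun(res, valid)
  H <- grid$image_dim[1]; W <- grid$image_dim[2]
  dense <- lapply(comps, function(V) {
    V[!valid] <- NA_real_
    grid_to_dense(grid$rows, grid$cols, V, H, W)
  })
  mask <- Reduce(`&`, lapply(dense, is.finite))
  dense <- lapply(dense, function(m) { m[!mask] <- 0; m })
  strain_field(dense$exx, dense$exy, dense$eyy, mask)
}

#' Subset-based DIC strain estimation
#'
#' Tracks each subset with an integer NCC search plus Gauss-Newton affine
#' refinement, then differentiates the resulting displacement grid: strain
#' at each centre comes from a least-squares plane fit of (u, v) over the
#' 3x3 neighbourhood of centres.  A dense field is produced by bilinear
#' interpolation between centres; pixels outside the tracked region (or near
#' failed subsets) are invalid.
#'
#' @param frame_a,frame_b grayscale frames in \[0, 1\].
#' @param grid a [subset_grid()].
#' @return A `strain_field` with attribute `"displacement"` (list of centre
#'   u, v matrices).
#' @export
dic_track <- function(frame_a, frame_b, grid = NULL) {
  if (is.null(grid)) grid <- subset_grid(dim(frame_a))
  res <- track_subsets(frame_a, frame_b, grid)
  step <- grid$step
  field <- results_to_field(res, grid, function(res, valid) {
    nr <- dim(res)[1]; nc <- dim(res)[2]
    U <- res[, , 1]; V <- res[, , 2]
    U[!valid] <- NA; V[!valid] <- NA
    exx <- exy <- eyy <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr))
      for (j in seq_len(nc)) {
        ii <- max(1, i - 1):min(nr, i + 1)
        jj <- max(1, j - 1):min(nc, j + 1)
        pts <- expand.grid(di = ii, dj = jj)
        uu <- U[cbind(pts$di, pts$dj)]
        vv <- V[cbind(pts$di, pts$dj)]
        ok <- is.finite(uu) & is.finite(vv)
        if (sum(ok) < 5) next
        X <- cbind(1, (pts$dj[ok] - j) * step, (pts$di[ok] - i) * step)
        cu <- tryCatch(qr.solve(X, uu[ok]), error = function(e) NULL)
        cv <- tryCatch(qr.solve(X, vv[ok]), error = function(e) NULL)
        if (is.null(cu) || is.null(cv)) next
        exx[i, j] <- cu[2]               # du/dx
        eyy[i, j] <- cv[3]               # dv/dy
        exy[i, j] <- (cu[3] + cv[2]) / 2 # (du/dy + dv/dx)/2
      }
    list(exx = exx, exy = exy, eyy = eyy)
  })
  attr(field, "displacement") <- list(u = res[, , 1], v = res[, , 2],
                                      corr = res[, , 7])
  field
}

#' Direct deformation estimation (DDE)
#'
#' Identical subset tracking to [dic_track()], but strain is read directly
#' from the gradient part of each subset's converged affine warp,
#' \eqn{\epsilon = (F + F^T)/2 - I}, with no displacement differentiation.
#'
#' @inheritParams dic_track
#' @return A `strain_field`.
#' @export
dde_track <- function(frame_a, frame_b, grid = NULL) {
  if (is.null(grid)) grid <- subset_grid(dim(frame_a))
  res <- track_subsets(frame_a, frame_b, grid)
  results_to_field(res, grid, function(res, valid) {
    list(exx = res[, , 3],
         exy = (res[, , 4] + res[, , 5]) / 2,
         eyy = res[, , 6])
  })
}

#' Tune subset size and step on a reference case
#'
#' Grid search over subset sizes and steps selecting the configuration with
#' the lowest median strain error against ground truth on the supplied image
#' pair.
#'
#' @param frame_a,frame_b an image pair with known deformation.
#' @param truth ground-truth `strain_field` for the pair.
#' @param method `"dic"` or `"dde"`.
#' @param subset_sizes,steps candidate values.
#' @return List with `best` (subset_size, step, error) and `results`
#'   (data.frame over the whole grid).
#' @export
tune_subset_grid <- function(frame_a, frame_b, truth, method = c("dic", "dde"),
                             subset_sizes = c(21L, 31L, 41L),
                             steps = c(4L, 8L, 16L)) {
  method <- match.arg(method)
  fun <- if (method == "dic") dic_track else dde_track
  rows <- list()
  for (ss in subset_sizes)
    for (st in steps) {
      g <- tryCatch(subset_grid(dim(frame_a), subset_size = ss, step = st),
                    error = function(e) NULL)
      if (is.null(g)) next
      f <- fun(frame_a, frame_b, g)
      err <- if (any(f$valid_mask))
        median(spatial_strain_error(f, truth)[f$valid_mask]) else Inf
      rows[[length(rows) + 1]] <- data.frame(subset_size = ss, step = st,
                                             error = err)
    }
  results <- do.call(rbind, rows)
  best <- results[which.min(results$error), ]
  list(best = best, results = results)
}
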