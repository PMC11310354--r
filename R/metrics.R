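#' Per-pixel spatial strain error
#'
#' Frobenius norm of the full 2x2 tensor mismatch at each pixel,
#' \eqn{\sqrt{\sum_{i=1}^2\sum_{j=1}^2 (\hat\epsilon_{ij} -
#' \epsilon_{ij})^2}}; the symmetric off-diagonal component contributes
#' twice under the double sum.
#'
#' @param pred,truth `strain_field`s of equal shape.
#' @return Numeric matrix of non-negative errors.
#' @export
spatial_strain_error <- function(pred, truth) {
  if (!identical(dim(pred$exx), dim(truth$exx)))
    stop("pred and truth shapes differ")
  sqrt((pred$exx - truth$exx)^2 +
         2 * (pred$exy - truth$exy)^2 +
         (pred$eyy - truth$eyy)^2)
}

#' Per-frame strain error
#'
#' Median of the spatial strain error over the overlap mask, with first and
#' third quartiles.
#'
#' @param spatial_map matrix from [spatial_strain_error()].
#' @param overlap_mask logical matrix of pixels to pool.
#' @return List with `median`, `q1`, `q3`.
#' @export
strain_error <- function(spatial_map, overlap_mask) {
  if (!any(overlap_mask)) stop("overlap mask is empty")
  v <- spatial_map[overlap_mask]
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Median strain error over a full cycle
#'
#' Pooled median of the spatial strain error over all overlap pixels of all
#' frames (a single median over the pooled (pixel, frame) set, not a median
#' of per-frame medians).
#'
#' @param spatial_maps list of matrices, one per frame.
#' @param overlap_mask logical matrix shared by all frames.
#' @return Scalar pooled median.
#' @export
median_strain_error <- function(spatial_maps, overlap_mask) {
  if (length(spatial_maps) < 1) stop("need at least one frame")
  if (!any(overlap_mask)) stop("overlap mask is empty")
  pool <- unlist(lapply(spatial_maps, function(m) m[overlap_mask]))
  median(pool)
}

#' Intersection of validity masks
#'
#' The shared region where every compared method produced a valid estimate.
#'
#' @param masks list of logical matrices of one shape.
#' @return Logical matrix; errors if the intersection is empty, reporting
#'   per-mask pixel counts.
#' @export
overlap_mask <- function(masks) {
  if (length(masks) < 1) stop("need at least one mask")
  out <- masks[[1]]
  for (m in masks[-1]) {
    if (!identical(dim(m), dim(out))) stop("mask shapes differ")
    out <- out & m
  }
  if (!any(out))
    stop("empty overlap; per-mask valid counts: ",
         paste(vapply(masks, sum, numeric(1)), collapse = ", "))
  out
}

#' Score a sequence prediction against ground truth
#'
#' @param pred a `sequence_prediction` (or list of `strain_field`s).
#' @param truths list of ground-truth `strain_field`s, same length.
#' @param mask optional logical overlap mask; default the intersection of
#'   the predictions' validity masks.
#' @return List with `spatial_maps`, `per_frame` (data.frame of median/q1/q3
#'   per frame), `overall` (pooled median), `overlap_mask`.
#' @export
error_summary <- function(pred, truths, mask = NULL) {
  fields <- if (inherits(pred, "sequence_prediction")) pred$fields else pred
  if (length(fields) != length(truths))
    stop("prediction and truth lengths differ")
  if (is.null(mask))
    mask <- overlap_mask(lapply(fields, `[[`, "valid_mask"))
  maps <- lapply(seq_along(fields), function(t)
    spatial_strain_error(fields[[t]], truths[[t]]))
  pf <- do.call(rbind, lapply(seq_along(maps), function(t) {
    se <- strain_error(maps[[t]], mask)
    data.frame(frame = t, median = se$median, q1 = se$q1, q3 = se$q3)
  }))
  list(spatial_maps = maps, per_frame = pf,
       overall = median_strain_error(maps, mask), overlap_mask = mask)
}

#' Permutation test for a difference in median error
#'
#' Two-sided permutation test of the difference in sample medians between
#' two error samples, with the add-one estimator
#' \eqn{p = (1 + \#\{|\Delta_{perm}| \ge |\Delta_{obs}|\}) / (n_{perm}+1)}.
#'
#' @param errors_a,errors_b numeric vectors of per-pixel errors.
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed.
#' @return List with `p_value`, `observed` (median difference a - b),
#'   `n_perm`.
#' @export
permutation_test <- function(errors_a, errors_b, n_perm = 10000L, seed = 1L) {
  if (!length(errors_a) || !length(errors_b))
    stop("both samples must be non-empty")
  if (n_perm < 100)
    message("permutation_test: n_perm < 100 gives a coarse p-value")
  obs <- median(errors_a) - median(errors_b)
  pool <- c(errors_a, errors_b)
  na <- length(errors_a)
  n <- length(pool)
  cnt <- with_seed(seed, {
    hits <- 0L
    for (k in seq_len(n_perm)) {
      idx <- sample.int(n, na)
      d <- median(pool[idx]) - median(pool[-idx])
      if (abs(d) >= abs(obs) - 1e-15) hits <- hits + 1L
    }
    hits
  })
  list(p_value = (1 + cnt) / (n_perm + 1), observed = obs,
       n_perm = as.integer(n_perm))
}
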