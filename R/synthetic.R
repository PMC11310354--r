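#' Default deformation parameter ranges for training-set generation
#'
#' Tension and compression deep-edge strains are drawn uniformly from ranges
#' covering the 4-16% benchmark span; magnitudes below 1% are excluded since
#' they are not meaningfully distinguishable from rigid motion at speckle
#' scale.  Rigid samples translate by up to 5 px per axis.
#' @return Named list of ranges.
#' @export
default_deformation_ranges <- function() {
  list(tension = c(0.01, 0.16),
       compression = c(-0.16, -0.01),
       rigid_shift = c(-5, 5))
}

#' Default noise-strength ranges for training-set generation
#'
#' Each synthetic frame receives noise whose strengths are sampled uniformly
#' from these ranges (speckle-multiplicative sd, additive Gaussian sd, global
#' gain and offset).
#' @return Named list of ranges.
#' @export
default_noise_ranges <- function() {
  list(speckle_sd = c(0, 0.12),
       gauss_sd = c(0, 0.04),
       gain = c(0.92, 1.08),
       offset = c(-0.04, 0.04))
}

#' @noRd
sample_noise_params <- function(ranges) {
  list(speckle_sd = runif(1, ranges$speckle_sd[1], ranges$speckle_sd[2]),
       gauss_sd = runif(1, ranges$gauss_sd[1], ranges$gauss_sd[2]),
       gain = runif(1, ranges$gain[1], ranges$gain[2]),
       offset = runif(1, ranges$offset[1], ranges$offset[2]))
}

#' Generate a synthetic training set of deformed speckle-image pairs
#'
#' Each sample draws a deformation class, a class-specific deformation
#' (uniform deep strain for tension/compression, uniform translation for
#' rigid), builds the prescribed strain field, integrates it to a
#' displacement field, forward-warps a fresh speckle substrate, and adds
#' independently sampled noise to both frames.  The exact prescribed field is
#' stored as ground truth (the zero field for rigid samples).
#'
#' @param n_pairs number of samples (>= 3).
#' @param class_mix length-3 proportions (tension, compression, rigid),
#'   summing to 1.
#' @param deformation_ranges see [default_deformation_ranges()].
#' @param noise_ranges see [default_noise_ranges()]; strengths are sampled
#'   uniformly per frame.
#' @param seed integer seed; the full dataset is reproducible from it.
#' @param height,width frame size in pixels.
#' @param geometry optional [tendon_geometry()]; default band geometry.
#' @param speckle_params forwarded to [generate_speckle_image()].
#' @return List of `synthetic_sample` objects with fields `image_ref`,
#'   `image_def`, `truth`, `cls`, `params`, `seed`.
#' @export
generate_training_set <- function(n_pairs,
                                  class_mix = c(1, 1, 1) / 3,
                                  deformation_ranges = default_deformation_ranges(),
                                  noise_ranges = default_noise_ranges(),
                                  seed = 1L,
                                  height = 64L, width = 64L,
                                  geometry = NULL,
                                  speckle_params = list()) {
  if (n_pairs < 3) stop("`n_pairs` must be at least 3")
  if (abs(sum(class_mix) - 1) > 1e-8 || length(class_mix) != 3)
    stop("`class_mix` must be three proportions summing to 1")
  for (rg in deformation_ranges[c("tension", "compression")])
    if (rg[2] < rg[1]) stop("empty deformation range")
  if (is.null(geometry)) geometry <- default_geometry(height, width)

  lapply(seq_len(n_pairs), function(i) {
    s <- derive_seed(seed, i)
    with_seed(s, {
      cls_idx <- sample.int(3, 1, prob = class_mix) - 1L
      cls <- deformation_class(cls_idx)
      params <- list()
      if (cls$label == "rigid") {
        sh <- runif(2, deformation_ranges$rigid_shift[1],
                    deformation_ranges$rigid_shift[2])
        params$shift <- sh
        truth <- zero_strain_field(height, width)
        disp <- displacement_field(matrix(sh[1], height, width),
                                   matrix(sh[2], height, width))
      } else {
        rg <- deformation_ranges[[cls$label]]
        eps <- runif(1, rg[1], rg[2])
        params$eps_deep <- eps
        truth <- build_strain_field(eps, geometry)
        disp <- strain_to_displacement(truth)
      }
      np_ref <- sample_noise_params(noise_ranges)
      np_def <- sample_noise_params(noise_ranges)
      params$noise_ref <- np_ref
      params$noise_def <- np_def
      substrate <- generate_speckle_image(height, width, speckle_params,
                                          seed = derive_seed(s, 1))
      deformed <- warp_image(substrate, disp)
      structure(list(
        image_ref = add_noise(substrate, np_ref, seed = derive_seed(s, 2)),
        image_def = add_noise(deformed, np_def, seed = derive_seed(s, 3)),
        truth = truth, cls = cls, params = params, seed = s),
        class = "synthetic_sample")
    })
  })
}

#' Default per-frame noise strengths of the benchmark test cases
#' @return Named list of fixed strengths and jitter half-widths.
#' @export
default_testcase_noise <- function() {
  list(speckle_sd = 0.08, gauss_sd = 0.025,
       gain_jitter = 0.03, offset_jitter = 0.02)
}

#' Generate benchmark test cases with known deformation
#'
#' One synthetic contraction-hold-relaxation sequence per maximum strain
#' level.  A single speckle substrate is warped so that the frame at time t
#' carries the prescribed field at deep strain
#' `level * temporal_profile(t)`; the stored ground truth for each frame is
#' cumulative strain relative to the first frame.  Independent noise is
#' added to every frame.
#'
#' @param levels maximum deep-layer longitudinal strains, each in (0, 0.5);
#'   default the five benchmark levels 4, 7, 10, 13, 16%.
#' @param protocol ramp/hold/relax durations in seconds.
#' @param fps frames per second (default 1).
#' @param seed integer seed.
#' @param height,width frame size.
#' @param geometry optional [tendon_geometry()].
#' @param noise list as [default_testcase_noise()]; per-frame gain/offset are
#'   jittered uniformly within the given half-widths.
#' @param noise_scale scalar multiplying all noise strengths (0 = noise-free,
#'   1 = default benchmark noise).
#' @return List of `test_case` objects with fields `sequence`, `truths`,
#'   `eps_long_max`, `protocol`, `times`, `eps_series`, `geometry`.
#' @export
generate_test_cases <- function(levels = c(0.04, 0.07, 0.10, 0.13, 0.16),
                                protocol = c(ramp = 3, hold = 5, relax = 3),
                                fps = 1, seed = 1L,
                                height = 64L, width = 64L,
                                geometry = NULL,
                                noise = default_testcase_noise(),
                                noise_scale = 1) {
  if (length(levels) == 0) stop("`levels` must be non-empty")
  if (any(levels <= 0 | levels >= 0.5)) stop("levels must lie in (0, 0.5)")
  if (is.null(geometry)) geometry <- default_geometry(height, width)
  total <- sum(protocol)
  times <- seq(0, total, by = 1 / fps)

  lapply(seq_along(levels), function(li) {
    lev <- levels[li]
    cseed <- derive_seed(seed, 1000 + li)
    substrate <- generate_speckle_image(height, width, seed = cseed)
    eps_series <- lev * temporal_profile(times, protocol)
    frames <- vector("list", length(times))
    truths <- vector("list", length(times) - 1L)
    for (k in seq_along(times)) {
      if (eps_series[k] == 0) {
        frame <- substrate
        truth <- zero_strain_field(height, width)
      } else {
        truth <- build_strain_field(eps_series[k], geometry)
        frame <- warp_image(substrate, strain_to_displacement(truth))
      }
      if (noise_scale > 0) {
        fs <- derive_seed(cseed, k)
        np <- with_seed(fs, list(
          speckle_sd = noise$speckle_sd * noise_scale,
          gauss_sd = noise$gauss_sd * noise_scale,
          gain = 1 + runif(1, -1, 1) * noise$gain_jitter * noise_scale,
          offset = runif(1, -1, 1) * noise$offset_jitter * noise_scale))
        frame <- add_noise(frame, np, seed = derive_seed(fs, 1))
      }
      frames[[k]] <- frame
      if (k > 1) truths[[k - 1L]] <- truth
    }
    structure(list(
      sequence = image_sequence(frames, frame_interval = 1 / fps),
      truths = truths, eps_long_max = lev, protocol = protocol,
      times = times, eps_series = eps_series, geometry = geometry),
      class = "test_case")
  })
}
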