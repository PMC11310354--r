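#' @noRd
reflect_pad_to <- function(img, mult) {
  d <- dim(img)
  th <- ceiling(d[1] / mult) * mult
  tw <- ceiling(d[2] / mult) * mult
  if (th == d[1] && tw == d[2]) return(list(img = img, crop = d))
  ri <- c(seq_len(d[1]), rev(seq_len(d[1])))[seq_len(th)]
  ci <- c(seq_len(d[2]), rev(seq_len(d[2])))[seq_len(tw)]
  list(img = img[ri, ci], crop = d)
}

#' Predict class and strain field for one image pair
#'
#' Stage one classifies the pair; stage two routes it to the regressor of
#' the predicted class and returns that network's full-field strain.  Frames
#' whose sides are not divisible by `2^depth` are reflection-padded before
#' the forward pass and the output is cropped back.
#'
#' @param models named list with elements `classifier`, `tension`,
#'   `compression`, `rigid` (as returned by [train_all()] or
#'   [load_checkpoint()]).
#' @param frame_a,frame_b grayscale matrices in \[0, 1\], equal shape.
#' @return List with `class` (a `deformation_class`) and `field` (a
#'   `strain_field`, valid everywhere).
#' @export
predict_pair <- function(models, frame_a, frame_b) {
  if (!identical(dim(frame_a), dim(frame_b))) stop("frame shapes differ")
  cls <- classify_pair(models$classifier, frame_a, frame_b)
  reg <- models[[cls$label]]
  if (is.null(reg)) stop("missing regressor for class ", cls$label)
  mult <- 2^reg$depth
  pa <- reflect_pad_to(frame_a, mult)
  pb <- reflect_pad_to(frame_b, mult)
  x <- pair_to_input(pa$img, pb$img)
  y <- regressor_forward(reg, x, training = FALSE)$y
  h <- pa$crop[1]; w <- pa$crop[2]
  field <- strain_field(y[seq_len(h), seq_len(w), 1, 1],
                        y[seq_len(h), seq_len(w), 2, 1],
                        y[seq_len(h), seq_len(w), 3, 1])
  list(class = cls, field = field)
}

#' Predict strain fields over an image sequence
#'
#' In `"reference"` mode (default) every frame is paired with the first
#' frame, so each prediction is directly the cumulative strain relative to
#' frame 1.  In `"incremental"` mode consecutive frames are paired and the
#' per-step strain is composed into cumulative strain: diagonal components
#' compose multiplicatively as stretch ratios
#' (\eqn{1+\epsilon \leftarrow (1+\epsilon_{step})(1+\epsilon_{cum})}) and
#' shear accumulates additively (a small-strain approximation).
#'
#' @param models named model list (see [predict_pair()]).
#' @param sequence an [image_sequence()] with T >= 2 frames.
#' @param reference_mode `"reference"` or `"incremental"`.
#' @return An object of class `sequence_prediction`: list with `fields` and
#'   `classes` (each of length T-1) and `reference_mode`.
#' @export
predict_sequence <- function(models, sequence,
                             reference_mode = c("reference", "incremental")) {
  reference_mode <- match.arg(reference_mode)
  Tn <- length(sequence$frames)
  if (Tn < 2) stop("sequence must have at least two frames")
  fields <- vector("list", Tn - 1L)
  classes <- vector("list", Tn - 1L)
  if (reference_mode == "reference") {
    for (t in seq_len(Tn - 1L)) {
      pr <- predict_pair(models, sequence$frames[[1]],
                         sequence$frames[[t + 1L]])
      fields[[t]] <- pr$field
      classes[[t]] <- pr$class
    }
  } else {
    cum <- NULL
    for (t in seq_len(Tn - 1L)) {
      pr <- predict_pair(models, sequence$frames[[t]],
                         sequence$frames[[t + 1L]])
      classes[[t]] <- pr$class
      step <- pr$field
      cum <- if (is.null(cum)) step else compose_strain(cum, step)
      fields[[t]] <- cum
    }
  }
  structure(list(fields = fields, classes = classes,
                 reference_mode = reference_mode),
            class = "sequence_prediction")
}

#' Compose two strain states
#'
#' Per-axis stretch-ratio multiplication for the diagonal components and
#' additive shear; the small-strain composition used by incremental
#' accumulation.
#'
#' @param cum,step `strain_field`s of equal shape.
#' @return Composed `strain_field`.
#' @export
compose_strain <- function(cum, step) {
  strain_field((1 + step$exx) * (1 + cum$exx) - 1,
               step$exy + cum$exy,
               (1 + step$eyy) * (1 + cum$eyy) - 1,
               cum$valid_mask & step$valid_mask)
}
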