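#' Read an image stack from disk
#'
#' Loads a directory of numerically-sorted TIFF/PNG frames, or a single
#' multi-page TIFF, as a grayscale [image_sequence()].  Integer images are
#' rescaled by their type maximum to \[0, 1\]; RGB inputs are converted to
#' grayscale with luminance weights (0.299, 0.587, 0.114).  Frame ordering
#' is natural-numeric ("frame2" before "frame10").
#'
#' @param path directory of frames or a multi-page TIFF file.
#' @param pixel_spacing,frame_interval metadata, read from a `sidecar.json`
#'   in the directory when present (keys `pixel_spacing_mm`,
#'   `frame_interval_s`), otherwise from these arguments.
#' @return An [image_sequence()].
#' @export
read_image_stack <- function(path, pixel_spacing = 0.05, frame_interval = 1) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$",
                        ignore.case = TRUE)
    if (!length(files)) stop("no TIFF/PNG frames found in ", path)
    files <- natural_sort(files)
    frames <- lapply(file.path(path, files), read_gray)
    side <- file.path(path, "sidecar.json")
    if (file.exists(side)) {
      meta <- jsonlite::read_json(side)
      pixel_spacing <- meta$pixel_spacing_mm %||% pixel_spacing
      frame_interval <- meta$frame_interval_s %||% frame_interval
    }
  } else if (file.exists(path)) {
    raw <- tiff::readTIFF(path, all = TRUE)
    frames <- lapply(raw, to_gray)
  } else stop("path does not exist: ", path)
  shapes <- vapply(frames, function(f) paste(dim(f), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) > 1)
    stop("mixed frame shapes: ", paste(unique(shapes), collapse = ", "))
  image_sequence(frames, pixel_spacing = pixel_spacing,
                 frame_interval = frame_interval)
}

#' @noRd
read_gray <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(file)
  else png::readPNG(file)
  to_gray(img)
}

#' @noRd
to_gray <- function(img) {
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3)
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img <- img[, , 1]
  }
  pmin(pmax(img, 0), 1)
}

#' Write an image sequence as 16-bit grayscale TIFF frames
#'
#' @param sequence an [image_sequence()].
#' @param dir output directory (created if needed).
#' @param prefix frame filename prefix.
#' @return The directory, invisibly.
#' @export
write_image_stack <- function(sequence, dir, prefix = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nd <- nchar(as.character(length(sequence$frames)))
  for (k in seq_along(sequence$frames)) {
    f <- file.path(dir, sprintf("%s%0*d.tiff", prefix, nd, k))
    tiff::writeTIFF(sequence$frames[[k]], f, bits.per.sample = 16L)
  }
  jsonlite::write_json(list(pixel_spacing_mm = sequence$pixel_spacing,
                            frame_interval_s = sequence$frame_interval),
                       file.path(dir, "sidecar.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Write / read a strain-field container
#'
#' A container directory holds the per-frame strain arrays (exx, exy, eyy,
#' valid mask) as one compressed serialised archive plus a JSON manifest
#' (shape, number of frames, reference mode, seed, format version).
#' Read-back is lossless.
#'
#' @param fields list of `strain_field`s (or a `sequence_prediction`).
#' @param path container directory.
#' @param manifest named list of extra manifest entries (e.g.
#'   `reference_mode`, `seed`).
#' @param overwrite overwrite an existing container (default FALSE).
#' @return `write_strain_container` returns `path` invisibly;
#'   `read_strain_container` returns a list with `fields` and `manifest`.
#' @export
write_strain_container <- function(fields, path, manifest = list(),
                                   overwrite = FALSE) {
  if (inherits(fields, "sequence_prediction")) {
    manifest$reference_mode <- manifest$reference_mode %||%
      fields$reference_mode
    fields <- fields$fields
  }
  if (dir.exists(path) && !overwrite)
    stop("container exists; use overwrite = TRUE")
  for (f in fields)
    if (!all(is.finite(c(f$exx[f$valid_mask], f$eyy[f$valid_mask]))))
      stop("non-finite strain values in a field")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(fields[[1]]$exx)
  manifest <- modifyList(list(format = "strainkit-strain", version = 1L,
                              shape = d, n_frames = length(fields)),
                         manifest)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE)
  saveRDS(fields, file.path(path, "fields.rds"), compress = "gzip")
  invisible(path)
}

#' @rdname write_strain_container
#' @export
read_strain_container <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a strain container: ", path)
  manifest <- jsonlite::read_json(mf)
  if (!identical(manifest$format, "strainkit-strain"))
    stop("unrecognised container format")
  list(fields = readRDS(file.path(path, "fields.rds")), manifest = manifest)
}

#' Read a force trace CSV
#'
#' Expects columns `time_s` and `grip_force_N`; extra columns
#' (`effort_level`, `mvc_N`) are carried through.
#'
#' @param file CSV path.
#' @return A data.frame with strictly increasing `time_s` and non-negative
#'   `grip_force_N`.
#' @export
read_force_trace <- function(file) {
  df <- utils::read.csv(file)
  if (!all(c("time_s", "grip_force_N") %in% names(df)))
    stop("force trace needs columns time_s, grip_force_N")
  if (is.unsorted(df$time_s, strictly = TRUE))
    stop("time_s must be strictly increasing")
  if (any(df$grip_force_N < 0)) stop("grip_force_N must be non-negative")
  df
}

#' Load a YAML run configuration
#'
#' @param file YAML file with blocks among `image`, `geometry`,
#'   `deformation`, `noise`, `protocol`, `counts`, `training`; unknown
#'   top-level keys are rejected.
#' @return Named list.
#' @export
read_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  known <- c("image", "geometry", "deformation", "noise", "protocol",
             "counts", "training", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg
}
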