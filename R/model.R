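# Two-stage model: a convolutional deformation classifier and UNet-style
# strain regressors.  Both are plain parameter lists plus hand-derived
# forward/backward passes built on the primitives in nn.R.

#' Stack and normalise an image pair as network input
#'
#' Each image is min-max normalised to \[0, 1\] independently, then the two
#' are stacked as channels.
#'
#' @param frame_a,frame_b numeric matrices of equal shape.
#' @return Array (H, W, 2, 1).
#' @export
pair_to_input <- function(frame_a, frame_b) {
  if (!identical(dim(frame_a), dim(frame_b))) stop("frame shapes differ")
  if (!all(is.finite(frame_a)) || !all(is.finite(frame_b)))
    stop("frames must be finite")
  mm <- function(x) {
    rg <- range(x)
    if (rg[2] > rg[1]) (x - rg[1]) / (rg[2] - rg[1]) else x * 0
  }
  array(c(mm(frame_a), mm(frame_b)), c(dim(frame_a), 2L, 1L))
}

#' @noRd
stack_inputs <- function(inputs) {
  d <- dim(inputs[[1]])
  out <- array(0, c(d[1], d[2], d[3], length(inputs)))
  for (k in seq_along(inputs)) out[, , , k] <- inputs[[k]]
  out
}

#' Build the deformation classifier
#'
#' Convolution / batch-norm / ReLU / max-pool blocks followed by a
#' fully-connected head with three output logits (tension, compression,
#' rigid).  Weights are reproducibly initialised from `seed`.
#'
#' @param depth number of conv-pool blocks (>= 2).
#' @param widths channel widths per block (length `depth`).
#' @param input_size expected (H, W) of input frames; must be divisible by
#'   `2^depth`.
#' @param hidden width of the fully-connected hidden layer.
#' @param seed integer seed for initialisation.
#' @return An object of class `strain_classifier`.
#' @export
build_classifier <- function(depth = 4, widths = c(8, 16, 32, 32),
                             input_size = c(64, 64), hidden = 64, seed = 1L) {
  if (depth < 2) stop("`depth` must be at least 2")
  if (length(widths) != depth) stop("`widths` must have length `depth`")
  if (any(input_size %% 2^depth != 0))
    stop(sprintf("input sides must be divisible by 2^%d", depth))
  with_seed(seed, {
    params <- list()
    cin <- 2L
    for (i in seq_len(depth)) {
      params[[paste0("conv", i)]] <- conv_init(cin, widths[i])
      params[[paste0("bn", i)]] <- bn_init(widths[i])
      cin <- widths[i]
    }
    feat <- prod(input_size / 2^depth) * widths[depth]
    params$fc1 <- dense_init(feat, hidden)
    params$fc2 <- dense_init(hidden, 3L, sd = 0.01)
    structure(list(params = params, depth = depth, widths = widths,
                   input_size = input_size, hidden = hidden, seed = seed),
              class = "strain_classifier")
  })
}

#' @noRd
classifier_forward <- function(model, x, training = FALSE) {
  p <- model$params
  cache <- list(x0 = x)
  for (i in seq_len(model$depth)) {
    cv <- conv_fwd(x, p[[paste0("conv", i)]])
    bn <- bn_fwd(cv, p[[paste0("bn", i)]], training = training)
    p[[paste0("bn", i)]] <- bn$p
    rl <- relu_fwd(bn$y)
    pl <- pool_fwd(rl$y)
    cache[[paste0("blk", i)]] <- list(x_in = x, conv = cv, bn = bn, relu = rl,
                                      pool = pl)
    x <- pl$y
  }
  d <- dim(x)
  flat <- matrix(x, nrow = prod(d[1:3]), ncol = d[4])
  h <- dense_fwd(flat, p$fc1)
  hr <- relu_fwd(h)
  logits <- dense_fwd(hr$y, p$fc2)
  cache$flat <- flat; cache$flat_dim <- d; cache$h <- h; cache$hr <- hr
  list(logits = logits, probs = softmax_cols(logits), cache = cache,
       bn_params = p[grep("^bn", names(p))])
}

# backward from dlogits (3 x B); returns grads mirroring model$params
#' @noRd
classifier_backward <- function(model, fwd, dlogits) {
  p <- model$params
  g <- list()
  db2 <- dense_bwd(fwd$cache$hr$y, p$fc2, dlogits)
  g$fc2 <- list(w = db2$dw, b = db2$db)
  dh <- relu_bwd(db2$dx, fwd$cache$hr$mask)
  db1 <- dense_bwd(fwd$cache$flat, p$fc1, dh)
  g$fc1 <- list(w = db1$dw, b = db1$db)
  dx <- array(db1$dx, fwd$cache$flat_dim)
  for (i in rev(seq_len(model$depth))) {
    blk <- fwd$cache[[paste0("blk", i)]]
    dpool <- pool_bwd(dx, blk$pool)
    drelu <- relu_bwd(dpool, blk$relu$mask)
    dbn <- bn_bwd(drelu, blk$bn, p[[paste0("bn", i)]]$gamma)
    g[[paste0("bn", i)]] <- list(gamma = dbn$dgamma, beta = dbn$dbeta)
    dcv <- conv_bwd(blk$x_in, p[[paste0("conv", i)]], dbn$dx)
    g[[paste0("conv", i)]] <- list(w = dcv$dw, b = dcv$db)
    dx <- dcv$dx
  }
  g
}

#' Build a strain regression network
#'
#' UNet-style encoder-decoder: single conv/batch-norm/ReLU block per scale in
#' the encoder, 2x2 max-pool downsampling, a bottleneck block, and a decoder
#' with nearest-neighbour upsampling, skip concatenation from the matching
#' encoder scale, and conv/batch-norm/ReLU blocks.  A final linear 1x1
#' convolution maps to the three strain channels
#' (\eqn{\epsilon_{xx}, \epsilon_{xy}, \epsilon_{yy}}), unconstrained in sign.
#'
#' @param depth number of encoder scales before the bottleneck (default 3).
#' @param widths encoder channel widths (length `depth`); the bottleneck uses
#'   `2 * widths[depth]`.
#' @param skip logical, include skip connections (default TRUE).
#' @param seed integer seed for initialisation.
#' @return An object of class `strain_regressor`.
#' @export
build_regressor <- function(depth = 3, widths = c(8, 16, 32), skip = TRUE,
                            seed = 1L) {
  if (length(widths) != depth) stop("`widths` must have length `depth`")
  wb <- 2L * widths[depth]
  with_seed(seed, {
    params <- list()
    cin <- 2L
    for (i in seq_len(depth)) {
      params[[paste0("enc", i)]] <- conv_init(cin, widths[i])
      params[[paste0("ebn", i)]] <- bn_init(widths[i])
      cin <- widths[i]
    }
    params$bott <- conv_init(widths[depth], wb)
    params$bbn <- bn_init(wb)
    cin <- wb
    for (i in rev(seq_len(depth))) {
      cc <- cin + if (skip) widths[i] else 0L
      params[[paste0("dec", i)]] <- conv_init(cc, widths[i])
      params[[paste0("dbn", i)]] <- bn_init(widths[i])
      cin <- widths[i]
    }
    params$head <- conv1x1_init(widths[1], 3L)
    structure(list(params = params, depth = depth, widths = widths,
                   bottleneck = wb, skip = skip, seed = seed),
              class = "strain_regressor")
  })
}

#' @noRd
regressor_forward <- function(model, x, training = FALSE) {
  p <- model$params
  depth <- model$depth
  if (any(dim(x)[1:2] %% 2^depth != 0))
    stop(sprintf("input sides must be divisible by 2^%d", depth))
  cache <- list()
  enc_out <- vector("list", depth)
  for (i in seq_len(depth)) {
    cv <- conv_fwd(x, p[[paste0("enc", i)]])
    bn <- bn_fwd(cv, p[[paste0("ebn", i)]], training = training)
    p[[paste0("ebn", i)]] <- bn$p
    rl <- relu_fwd(bn$y)
    pl <- pool_fwd(rl$y)
    cache[[paste0("enc", i)]] <- list(x_in = x, bn = bn, relu = rl, pool = pl)
    enc_out[[i]] <- rl$y
    x <- pl$y
  }
  cv <- conv_fwd(x, p$bott)
  bn <- bn_fwd(cv, p$bbn, training = training)
  p$bbn <- bn$p
  rl <- relu_fwd(bn$y)
  cache$bott <- list(x_in = x, bn = bn, relu = rl)
  x <- rl$y
  for (i in rev(seq_len(depth))) {
    up <- upsample2_fwd(x)
    xin <- if (model$skip) concat_chan(up, enc_out[[i]]) else up
    cv <- conv_fwd(xin, p[[paste0("dec", i)]])
    bn <- bn_fwd(cv, p[[paste0("dbn", i)]], training = training)
    p[[paste0("dbn", i)]] <- bn$p
    rl <- relu_fwd(bn$y)
    cache[[paste0("dec", i)]] <- list(x_in = xin, up_dim = dim(up), bn = bn,
                                      relu = rl)
    x <- rl$y
  }
  y <- conv1x1_fwd(x, p$head)
  cache$head_in <- x
  list(y = y, cache = cache,
       bn_params = p[grep("bn", names(p))])
}

#' @noRd
regressor_backward <- function(model, fwd, dy) {
  p <- model$params
  depth <- model$depth
  g <- list()
  hb <- conv1x1_bwd(fwd$cache$head_in, p$head, dy)
  g$head <- list(w = hb$dw, b = hb$db)
  dx <- hb$dx
  dskip <- vector("list", depth)
  for (i in seq_len(depth)) {       # dec1 runs last in forward, first here
    blk <- fwd$cache[[paste0("dec", i)]]
    drelu <- relu_bwd(dx, blk$relu$mask)
    dbn <- bn_bwd(drelu, blk$bn, p[[paste0("dbn", i)]]$gamma)
    g[[paste0("dbn", i)]] <- list(gamma = dbn$dgamma, beta = dbn$dbeta)
    dcv <- conv_bwd(blk$x_in, p[[paste0("dec", i)]], dbn$dx)
    g[[paste0("dec", i)]] <- list(w = dcv$dw, b = dcv$db)
    nc_up <- blk$up_dim[3]
    dup <- dcv$dx[, , seq_len(nc_up), , drop = FALSE]
    if (model$skip)
      dskip[[i]] <- dcv$dx[, , nc_up + seq_len(model$widths[i]), ,
                           drop = FALSE]
    dx <- upsample2_bwd(dup)
  }
  blk <- fwd$cache$bott
  drelu <- relu_bwd(dx, blk$relu$mask)
  dbn <- bn_bwd(drelu, blk$bn, p$bbn$gamma)
  g$bbn <- list(gamma = dbn$dgamma, beta = dbn$dbeta)
  dcv <- conv_bwd(blk$x_in, p$bott, dbn$dx)
  g$bott <- list(w = dcv$dw, b = dcv$db)
  dx <- dcv$dx
  for (i in rev(seq_len(depth))) {
    blk <- fwd$cache[[paste0("enc", i)]]
    dpool <- pool_bwd(dx, blk$pool)
    drelu_in <- dpool
    if (model$skip && !is.null(dskip[[i]]))
      drelu_in <- drelu_in + dskip[[i]]
    drelu <- relu_bwd(drelu_in, blk$relu$mask)
    dbn <- bn_bwd(drelu, blk$bn, p[[paste0("ebn", i)]]$gamma)
    g[[paste0("ebn", i)]] <- list(gamma = dbn$dgamma, beta = dbn$dbeta)
    dcv <- conv_bwd(blk$x_in, p[[paste0("enc", i)]], dbn$dx)
    g[[paste0("enc", i)]] <- list(w = dcv$dw, b = dcv$db)
    dx <- dcv$dx
  }
  g
}

#' Number of trainable parameters of a model
#' @param model a `strain_classifier` or `strain_regressor`.
#' @return Integer count (batch-norm running statistics excluded).
#' @export
n_parameters <- function(model) {
  cnt <- 0L
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    keep <- setdiff(names(p), c("run_mean", "run_var"))
    cnt <- cnt + sum(vapply(p[keep], length, integer(1)))
  }
  cnt
}

# reflect-pad (if smaller) and centre-crop (if larger) to a fixed size
#' @noRd
fit_to_size <- function(img, size) {
  d <- dim(img)
  idx <- function(n, target) {
    if (n >= target) {
      off <- (n - target) %/% 2L
      seq_len(target) + off
    } else c(seq_len(n), rev(seq_len(n)))[seq_len(target)]
  }
  img[idx(d[1], size[1]), idx(d[2], size[2])]
}

#' Classify an image pair
#'
#' Runs the deformation classifier in evaluation mode and returns the argmax
#' class; ties break towards the lowest class index
#' (tension < compression < rigid).  Frames that do not match the
#' classifier's configured input size are reflection-padded or
#' centre-cropped to it (the class decision is global, so a central view
#' suffices).
#'
#' @param model a trained `strain_classifier`.
#' @param frame_a,frame_b the image pair (matrices in \[0, 1\]).
#' @return A `deformation_class` with attribute `"probs"`.
#' @export
classify_pair <- function(model, frame_a, frame_b) {
  if (!identical(dim(frame_a), as.integer(model$input_size))) {
    frame_a <- fit_to_size(frame_a, model$input_size)
    frame_b <- fit_to_size(frame_b, model$input_size)
  }
  x <- pair_to_input(frame_a, frame_b)
  fwd <- classifier_forward(model, x, training = FALSE)
  probs <- as.numeric(fwd$probs)
  idx <- which(probs == max(probs))[1] - 1L    # tie -> lowest index
  cls <- deformation_class(idx)
  attr(cls, "probs") <- probs
  cls
}

#' Save / load model checkpoints
#'
#' A checkpoint is a directory with a JSON header (architecture config,
#' seed, format version) and a serialised parameter archive.
#'
#' @param models named list of models (e.g. the result of [train_all()]).
#' @param path checkpoint directory.
#' @param overwrite overwrite an existing checkpoint (default FALSE).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the named list of models.
#' @export
save_checkpoint <- function(models, path, overwrite = FALSE) {
  if (dir.exists(path) && !overwrite)
    stop("checkpoint exists; use overwrite = TRUE")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  header <- list(format = "strainkit-checkpoint", version = 1L,
                 names = names(models),
                 classes = vapply(models, function(m) class(m)[1],
                                  character(1)))
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE)
  saveRDS(models, file.path(path, "weights.rds"), compress = "gzip")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  hf <- file.path(path, "header.json")
  if (!file.exists(hf)) stop("not a checkpoint directory: ", path)
  header <- jsonlite::read_json(hf)
  if (!identical(header$format, "strainkit-checkpoint"))
    stop("unrecognised checkpoint format")
  readRDS(file.path(path, "weights.rds"))
}
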