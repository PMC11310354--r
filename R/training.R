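#' Cross-entropy loss for the deformation classifier
#'
#' \eqn{-\sum_i y_i \log p_i} with one-hot truth over the three deformation
#' classes.  Probabilities are clipped to \[1e-12, 1\] before the log.
#'
#' @param probs length-3 probability vector (simplex point).
#' @param label a `deformation_class`, class label, or index 0/1/2.
#' @return Non-negative scalar.
#' @export
cross_entropy <- function(probs, label) {
  if (length(probs) != 3) stop("`probs` must have length 3")
  if (any(probs < -1e-9) || abs(sum(probs) - 1) > 1e-6)
    stop("`probs` must lie on the probability simplex")
  if (!inherits(label, "deformation_class")) label <- deformation_class(label)
  -log(max(min(probs[label$index + 1L], 1), 1e-12))
}

#' @noRd
field_to_array <- function(field) {
  array(c(field$exx, field$exy, field$eyy), c(dim(field$exx), 3L, 1L))
}

#' @noRd
fields_to_batch <- function(fields) {
  d <- dim(fields[[1]]$exx)
  out <- array(0, c(d[1], d[2], 3L, length(fields)))
  for (k in seq_along(fields)) {
    out[, , 1, k] <- fields[[k]]$exx
    out[, , 2, k] <- fields[[k]]$exy
    out[, , 3, k] <- fields[[k]]$eyy
  }
  out
}

#' Mean l2 strain loss
#'
#' Mean over examples and pixels of the squared Frobenius mismatch of the
#' full 2x2 strain tensor,
#' \eqn{\frac{1}{N}\frac{1}{P}\sum_n\sum_p\sum_{i=1}^2\sum_{j=1}^2
#' |\hat\epsilon_{ij} - \epsilon_{ij}|^2}.  The three stored channels expand
#' to the symmetric tensor with \eqn{\epsilon_{yx} = \epsilon_{xy}}, so the
#' shear mismatch is counted twice (once at ij = 12 and once at ij = 21).
#'
#' @param pred,truth lists of `strain_field`s, single `strain_field`s, or
#'   (H, W, 3, B) arrays with channels in order exx, exy, eyy.
#' @return Non-negative scalar.
#' @export
mean_l2_loss <- function(pred, truth) {
  pa <- as_field_batch(pred)
  ta <- as_field_batch(truth)
  if (!identical(dim(pa), dim(ta))) stop("pred and truth shapes differ")
  d <- dim(pa)
  diff2 <- (pa - ta)^2
  w <- c(1, 2, 1)   # shear channel appears at both off-diagonal positions
  tot <- 0
  for (ch in 1:3) tot <- tot + w[ch] * sum(diff2[, , ch, ])
  tot / (d[4] * d[1] * d[2])
}

#' @noRd
as_field_batch <- function(x) {
  if (inherits(x, "strain_field")) return(field_to_array(x))
  if (is.list(x)) return(fields_to_batch(x))
  if (is.array(x) && length(dim(x)) == 4L) return(x)
  stop("expected strain_field(s) or an (H, W, 3, B) array")
}

#' Stratified train/validation split
#'
#' Random split reproducible from `seed`, stratified by deformation class so
#' every class appears in both subsets even at small scale.  The total
#' training size is `ceiling((1 - val_fraction) * n)` within rounding per
#' stratum.
#'
#' @param samples list of `synthetic_sample`s.
#' @param val_fraction fraction held out for validation, in (0, 1).
#' @param seed integer seed.
#' @return List with elements `train` and `val` (disjoint, exhaustive).
#' @export
split_dataset <- function(samples, val_fraction = 0.2, seed = 1L) {
  if (length(samples) < 5) stop("need at least 5 samples to split")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("`val_fraction` must be in (0, 1)")
  labels <- vapply(samples, function(s) s$cls$label, character(1))
  with_seed(seed, {
    train_idx <- integer(0)
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      n_tr <- ceiling((1 - val_fraction) * length(idx))
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
    train_idx <- sort(train_idx)
    list(train = samples[train_idx],
         val = samples[setdiff(seq_along(samples), train_idx)])
  })
}

#' Training configuration
#'
#' @param profile `"tiny"` (CPU desk scale: 30 epochs, classifier batch 10)
#'   or `"full"` (100 epochs, classifier batch 100, larger widths).
#' @param learning_rate Adam learning rate for the strain regressors
#'   (default 2e-3 in the tiny profile, whose 30-epoch budget needs the
#'   faster schedule; 1e-3 at full scale).
#' @param classifier_lr Adam learning rate for the deformation classifier
#'   (default 2e-3; the classification task needs the faster schedule to
#'   separate sub-pixel rigid motion from ~1% strain within the epoch
#'   budget).
#' @param epochs training epochs.
#' @param batch_classifier,batch_regressor minibatch sizes.
#' @param val_fraction validation fraction (default 0.2).
#' @param seed integer seed for the split, initialisation, and shuffling.
#' @param classifier_widths,regressor_widths channel widths.
#' @return A `training_config` list.
#' @export
training_config <- function(profile = c("tiny", "full"),
                            learning_rate = NULL,
                            classifier_lr = 2e-3,
                            epochs = NULL,
                            batch_classifier = NULL,
                            batch_regressor = 10L,
                            val_fraction = 0.2,
                            seed = 1L,
                            classifier_widths = NULL,
                            regressor_widths = NULL) {
  profile <- match.arg(profile)
  tiny <- profile == "tiny"
  cfg <- list(
    profile = profile,
    learning_rate = learning_rate %||% (if (tiny) 2e-3 else 1e-3),
    classifier_lr = classifier_lr,
    epochs = epochs %||% (if (tiny) 30L else 100L),
    batch_classifier = batch_classifier %||% (if (tiny) 10L else 100L),
    batch_regressor = batch_regressor,
    val_fraction = val_fraction,
    seed = seed,
    classifier_widths = classifier_widths %||%
      (if (tiny) c(8, 16, 32) else c(16, 32, 64)),
    regressor_widths = regressor_widths %||%
      (if (tiny) c(8, 16, 32, 48) else c(16, 32, 64, 128)))
  if (cfg$batch_classifier < 1 || cfg$batch_regressor < 1)
    stop("batch sizes must be >= 1")
  if (cfg$val_fraction <= 0 || cfg$val_fraction >= 1)
    stop("`val_fraction` must be in (0, 1)")
  structure(cfg, class = "training_config")
}

#' @noRd
sample_inputs <- function(samples) {
  stack_inputs(lapply(samples, function(s)
    pair_to_input(s$image_ref, s$image_def)))
}

#' @noRd
classifier_predict_probs <- function(model, x) {
  classifier_forward(model, x, training = FALSE)$probs
}

#' @noRd
train_classifier <- function(samples_train, samples_val, cfg) {
  x_tr <- sample_inputs(samples_train)
  y_tr <- vapply(samples_train, function(s) s$cls$index, integer(1))
  x_va <- sample_inputs(samples_val)
  y_va <- vapply(samples_val, function(s) s$cls$index, integer(1))
  input_size <- dim(x_tr)[1:2]
  model <- build_classifier(widths = cfg$classifier_widths,
                            depth = length(cfg$classifier_widths),
                            input_size = input_size,
                            seed = derive_seed(cfg$seed, 11))
  opt <- adam_init(model$params)
  n <- length(samples_train)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric(), val_accuracy = numeric())
  best <- list(acc = -1, loss = Inf, params = model$params)
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 100 + ep), sample.int(n))
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = cfg$batch_classifier)) {
      idx <- ord[start:min(start + cfg$batch_classifier - 1, n)]
      xb <- x_tr[, , , idx, drop = FALSE]
      fwd <- classifier_forward(model, xb, training = TRUE)
      model$params[names(fwd$bn_params)] <- fwd$bn_params
      onehot <- matrix(0, 3, length(idx))
      onehot[cbind(y_tr[idx] + 1L, seq_along(idx))] <- 1
      pcl <- pmax(fwd$probs, 1e-12)
      ep_loss <- ep_loss + mean(-colSums(onehot * log(pcl)))
      nb <- nb + 1
      dlogits <- (fwd$probs - onehot) / length(idx)
      g <- classifier_backward(model, fwd, dlogits)
      st <- adam_step(opt, model$params, g, lr = cfg$classifier_lr)
      model$params <- st$params; opt <- st$state
    }
    pv <- classifier_predict_probs(model, x_va)
    onehot_v <- matrix(0, 3, length(y_va))
    onehot_v[cbind(y_va + 1L, seq_along(y_va))] <- 1
    val_loss <- mean(-colSums(onehot_v * log(pmax(pv, 1e-12))))
    val_acc <- mean(max.col(t(pv), ties.method = "first") - 1L == y_va)
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                 val_loss = val_loss, val_accuracy = val_acc))
    # retain the checkpoint with the best validation accuracy, breaking
    # ties by validation loss (accuracy is the quantity reported)
    if (val_acc > best$acc || (val_acc == best$acc && val_loss < best$loss))
      best <- list(acc = val_acc, loss = val_loss, params = model$params)
  }
  model$params <- best$params
  pv <- classifier_predict_probs(model, x_va)
  final_acc <- mean(max.col(t(pv), ties.method = "first") - 1L == y_va)
  list(model = model, log = log, val_accuracy = final_acc,
       val_loss = best$loss)
}

#' @noRd
train_regressor <- function(samples_train, samples_val, cfg, class_label,
                            seed_offset) {
  x_tr <- sample_inputs(samples_train)
  t_tr <- fields_to_batch(lapply(samples_train, `[[`, "truth"))
  x_va <- sample_inputs(samples_val)
  t_va <- fields_to_batch(lapply(samples_val, `[[`, "truth"))
  model <- build_regressor(widths = cfg$regressor_widths,
                           depth = length(cfg$regressor_widths),
                           seed = derive_seed(cfg$seed, seed_offset))
  opt <- adam_init(model$params)
  n <- length(samples_train)
  d <- dim(x_tr)
  P <- d[1] * d[2]
  wch <- array(rep(c(1, 2, 1), each = P), c(d[1], d[2], 3L, 1L))
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  best <- list(loss = Inf, params = model$params)
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, seed_offset * 1000 + ep),
                     sample.int(n))
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = cfg$batch_regressor)) {
      idx <- ord[start:min(start + cfg$batch_regressor - 1, n)]
      xb <- x_tr[, , , idx, drop = FALSE]
      tb <- t_tr[, , , idx, drop = FALSE]
      fwd <- regressor_forward(model, xb, training = TRUE)
      model$params[names(fwd$bn_params)] <- fwd$bn_params
      diff <- fwd$y - tb
      B <- length(idx)
      wb <- array(wch, c(d[1], d[2], 3L, B))
      ep_loss <- ep_loss + sum(wb * diff^2) / (B * P)
      nb <- nb + 1
      dy <- 2 * wb * diff / (B * P)
      g <- regressor_backward(model, fwd, dy)
      st <- adam_step(opt, model$params, g, lr = cfg$learning_rate)
      model$params <- st$params; opt <- st$state
    }
    pv <- regressor_forward(model, x_va, training = FALSE)$y
    val_loss <- mean_l2_loss(pv, t_va)
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                 val_loss = val_loss))
    if (val_loss < best$loss)
      best <- list(loss = val_loss, params = model$params)
  }
  model$params <- best$params
  list(model = model, log = log, val_loss = best$loss, class = class_label)
}

#' Train the full two-stage model
#'
#' Splits the dataset (stratified 80/20 by default), trains the deformation
#' classifier on all pairs with the cross-entropy loss, and trains one strain
#' regressor per deformation class on that class's samples with the mean l2
#' loss.  All four subnetworks use Adam; the checkpoint with the lowest
#' validation loss is retained for each.
#'
#' @param dataset list of `synthetic_sample`s containing all three classes.
#' @param config a [training_config()].
#' @return List with the four trained models (`classifier`, `tension`,
#'   `compression`, `rigid`) and a `report` (per-epoch logs, final validation
#'   accuracy and losses, wall-clock seconds, seed).
#' @export
train_all <- function(dataset, config = training_config()) {
  t0 <- proc.time()[["elapsed"]]
  labels <- vapply(dataset, function(s) s$cls$label, character(1))
  if (!all(deformation_classes() %in% labels))
    stop("dataset must contain all three deformation classes")
  sp <- split_dataset(dataset, config$val_fraction,
                      seed = derive_seed(config$seed, 7))
  lab_tr <- vapply(sp$train, function(s) s$cls$label, character(1))
  lab_va <- vapply(sp$val, function(s) s$cls$label, character(1))
  if (!all(deformation_classes() %in% lab_tr))
    stop("a deformation class is missing from the training split")

  clf <- train_classifier(sp$train, sp$val, config)
  regs <- list()
  for (k in seq_along(deformation_classes())) {
    lv <- deformation_classes()[k]
    regs[[lv]] <- train_regressor(sp$train[lab_tr == lv],
                                  sp$val[lab_va == lv],
                                  config, lv, seed_offset = 20 + k)
  }
  report <- list(
    classifier_log = clf$log,
    regressor_logs = lapply(regs, `[[`, "log"),
    val_accuracy = clf$val_accuracy,
    val_l2 = vapply(regs, `[[`, numeric(1), "val_loss"),
    elapsed_s = proc.time()[["elapsed"]] - t0,
    seed = config$seed,
    profile = config$profile)
  list(classifier = clf$model,
       tension = regs$tension$model,
       compression = regs$compression$model,
       rigid = regs$rigid$model,
       report = report)
}
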