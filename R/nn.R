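# Minimal CNN layer toolkit used by the classifier and the strain
# regressors.  Activations are 4-d arrays (H, W, C, B); compiled kernels do
# convolution and pooling, everything else is vectorised R.  Each *_fwd
# returns the output plus whatever the matching *_bwd needs.

#' @noRd
conv_init <- function(cin, cout, seed_stream, scale = NULL) {
  fan_in <- 9 * cin
  sd <- scale %||% sqrt(2 / fan_in)     # He initialisation for ReLU blocks
  list(w = matrix(rnorm(fan_in * cout, sd = sd), fan_in, cout),
       b = numeric(cout))
}

#' @noRd
conv_fwd <- function(x, p) .conv2d_forward(x, p$w, p$b)

#' @noRd
conv_bwd <- function(x, p, dy) .conv2d_backward(x, p$w, dy)

# 1x1 convolution as a channel-mixing matrix multiply
#' @noRd
conv1x1_init <- function(cin, cout, sd = 0.01) {
  list(w = matrix(rnorm(cin * cout, sd = sd), cin, cout), b = numeric(cout))
}

#' @noRd
conv1x1_fwd <- function(x, p) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])   # (H*W*B) x C
  y <- xm %*% p$w
  y <- sweep(y, 2, p$b, `+`)
  aperm(array(y, c(d[1], d[2], d[4], ncol(p$w))), c(1, 2, 4, 3))
}

#' @noRd
conv1x1_bwd <- function(x, p, dy) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = ncol(p$w))
  dxm <- dym %*% t(p$w)
  list(dx = aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3)),
       dw = crossprod(xm, dym), db = colSums(dym))
}

#' @noRd
relu_fwd <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(y = x, mask = mask)
}

#' @noRd
relu_bwd <- function(dy, mask) {
  dy[!mask] <- 0
  dy
}

#' @noRd
bn_init <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

# broadcast a per-channel vector over an (H, W, C, B) array
#' @noRd
bc_chan <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), times = d[4]), d)
}

#' @noRd
chan_mean <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])          # columns indexed by (c, b)
  cs <- colMeans(m)
  rowMeans(matrix(cs, nrow = d[3]))
}

#' @noRd
bn_fwd <- function(x, p, training = TRUE, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  if (training) {
    mu <- chan_mean(x)
    xc <- x - bc_chan(mu, d)
    v <- chan_mean(xc * xc)
    new_p <- p
    new_p$run_mean <- (1 - momentum) * p$run_mean + momentum * mu
    new_p$run_var <- (1 - momentum) * p$run_var + momentum * v
  } else {
    mu <- p$run_mean; v <- p$run_var
    xc <- x - bc_chan(mu, d)
    new_p <- p
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * bc_chan(istd, d)
  y <- xhat * bc_chan(p$gamma, d) + bc_chan(p$beta, d)
  list(y = y, xhat = xhat, istd = istd, p = new_p)
}

#' @noRd
bn_bwd <- function(dy, cache, gamma) {
  d <- dim(dy)
  dgamma <- chan_sum(dy * cache$xhat)
  dbeta <- chan_sum(dy)
  n <- d[1] * d[2] * d[4]
  t1 <- dy - bc_chan(dbeta / n, d) -
    cache$xhat * bc_chan(dgamma / n, d)
  dx <- t1 * bc_chan(gamma * cache$istd, d)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' @noRd
chan_sum <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])
  cs <- colSums(m)
  rowSums(matrix(cs, nrow = d[3]))
}

#' @noRd
pool_fwd <- function(x) {
  r <- .maxpool2_forward(x)
  r$in_dim <- dim(x)
  r
}

#' @noRd
pool_bwd <- function(dy, cache) .maxpool2_backward(dy, cache$idx, cache$in_dim)

#' @noRd
upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

#' @noRd
upsample2_bwd <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1, d[1], by = 2); i2 <- seq(2, d[1], by = 2)
  j1 <- seq(1, d[2], by = 2); j2 <- seq(2, d[2], by = 2)
  dy[i1, j1, , , drop = FALSE] + dy[i2, j1, , , drop = FALSE] +
    dy[i1, j2, , , drop = FALSE] + dy[i2, j2, , , drop = FALSE]
}

#' @noRd
concat_chan <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' @noRd
dense_init <- function(nin, nout, sd = NULL) {
  sd <- sd %||% sqrt(2 / nin)
  list(w = matrix(rnorm(nin * nout, sd = sd), nout, nin), b = numeric(nout))
}

# x: features x B
#' @noRd
dense_fwd <- function(x, p) p$w %*% x + p$b

#' @noRd
dense_bwd <- function(x, p, dy) {
  list(dx = crossprod(p$w, dy), dw = tcrossprod(dy, x), db = rowSums(dy))
}

#' @noRd
softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}

# ---- Adam -----------------------------------------------------------------

# Parameters and gradients are nested named lists of numeric arrays; the
# optimiser state mirrors that structure.
#' @noRd
adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else { z <- p; z[] <- 0; z }
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

#' @noRd
adam_step <- function(state, params, grads, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next   # frozen entries (e.g. BN running stats)
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}
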