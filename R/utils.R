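#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a deterministic child seed; keeps results independent across streams
# drawn from one user-facing seed.  Stays within 32-bit integer range.
#' @noRd
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1103 * as.double(k) + 12345) %% 2147483647)
}

# Cumulative trapezoidal integral of y sampled at unit spacing, anchored so
# the integral is zero at index `anchor` (1-based).
#' @noRd
cumtrapz_anchored <- function(y, anchor) {
  n <- length(y)
  inc <- (y[-n] + y[-1]) / 2
  cum <- c(0, cumsum(inc))
  cum - cum[anchor]
}

# C1 smoothstep on [0, 1]
#' @noRd
smoothstep <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  s * s * (3 - 2 * s)
}

#' @noRd
smoothstep_deriv <- function(s) {
  d <- 6 * s * (1 - s)
  d[s < 0 | s > 1] <- 0
  d
}

#' @noRd
stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
}

# Natural sort: orders "frame2" before "frame10".
#' @noRd
natural_sort <- function(x) {
  num <- suppressWarnings(as.numeric(gsub("\\D+", "", x)))
  ord <- order(is.na(num), num, x)
  x[ord]
}
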