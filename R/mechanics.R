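#' Bulk longitudinal strain over the hold period
#'
#' Pooled median of the longitudinal strain \eqn{\epsilon_{xx}} over tendon
#' pixels and all frames whose times fall inside the hold window.
#'
#' @param fields a `sequence_prediction` or list of `strain_field`s.
#' @param geometry a [tendon_geometry()] giving the tendon mask.
#' @param times frame times in seconds, one per field.
#' @param hold_window `c(t0, t1)` in seconds; defaults to the hold phase of
#'   the standard 3/5/3 protocol, `c(3, 8)`.
#' @return Scalar pooled median strain.
#' @export
bulk_longitudinal_strain <- function(fields, geometry, times,
                                     hold_window = c(3, 8)) {
  if (inherits(fields, "sequence_prediction")) fields <- fields$fields
  if (length(times) != length(fields))
    stop("`times` must give one time per field")
  sel <- which(times >= hold_window[1] & times <= hold_window[2])
  if (!length(sel)) stop("no frames inside the hold window")
  mask <- geometry$tendon_mask
  if (!any(mask)) stop("tendon mask is empty")
  pool <- unlist(lapply(fields[sel], function(f)
    f$exx[mask & f$valid_mask]))
  if (!length(pool)) stop("no valid tendon pixels in the hold window")
  median(pool)
}

#' Grip-to-tendon force transmission
#'
#' Linear map from measured grip force to tendon force,
#' `F_tendon = k * F_grip`.  The transmission coefficient summarises the
#' biomechanical moment-arm relation between grip and the finger flexor
#' tendon; it is a configurable input, default 0.25.
#'
#' @param grip_force grip force in N (vectorised, >= 0).
#' @param transmission list with coefficient `k` (> 0).
#' @return Tendon force in N.
#' @export
tendon_force <- function(grip_force, transmission = list(k = 0.25)) {
  if (any(grip_force < 0)) stop("grip force must be non-negative")
  k <- transmission$k %||% 0.25
  if (!is.numeric(k) || k <= 0) stop("transmission coefficient must be > 0")
  k * grip_force
}

#' Tendon stress
#'
#' Force divided by cross-sectional area; N / mm^2 = MPa.
#'
#' @param force tendon force in N (vectorised).
#' @param csa cross-sectional area in mm^2 (> 0).
#' @return Stress in MPa.
#' @export
stress <- function(force, csa) {
  if (!is.numeric(csa) || length(csa) != 1 || csa <= 0)
    stop("`csa` must be a positive scalar (mm^2)")
  force / csa
}

#' Apparent modulus from a stress-strain curve
#'
#' Scans all contiguous windows covering at least `window_fraction` of the
#' supplied loading-phase points and returns the slope of the
#' ordinary-least-squares line in the window with the highest coefficient of
#' determination (the "linear region").
#'
#' @param stress_series stress values in MPa (loading phase).
#' @param strain_series matching strain values (dimensionless).
#' @param window_fraction minimum window length as a fraction of the series
#'   (default 0.4).
#' @return List with `modulus` (MPa), `linear_region` (index range),
#'   `r_squared`, and `se` (standard error of the slope).
#' @export
apparent_modulus <- function(stress_series, strain_series,
                             window_fraction = 0.4) {
  n <- length(stress_series)
  if (length(strain_series) != n) stop("series lengths differ")
  if (n < 5) stop("need at least 5 loading-phase points")
  if (stats::sd(strain_series) < 1e-12)
    stop("strain series is constant; modulus undefined")
  wmin <- max(3L, ceiling(window_fraction * n))
  best <- NULL
  for (i0 in seq_len(n - wmin + 1L))
    for (i1 in seq(i0 + wmin - 1L, n)) {
      x <- strain_series[i0:i1]; y <- stress_series[i0:i1]
      sxx <- sum((x - mean(x))^2)
      if (sxx < 1e-24) next
      # closed-form simple OLS (avoids refitting lm over every window)
      slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
      res <- y - mean(y) - slope * (x - mean(x))
      tss <- sum((y - mean(y))^2)
      r2 <- if (tss > 0) 1 - sum(res^2) / tss else 1
      se <- sqrt(sum(res^2) / max(length(x) - 2L, 1L) / sxx)
      if (is.null(best) || r2 > best$r_squared + 1e-12)
        best <- list(modulus = slope, linear_region = c(i0, i1),
                     r_squared = r2, se = se)
    }
  if (is.null(best)) stop("no admissible window found")
  best
}

#' Regression of a response on effort level
#'
#' Ordinary least squares of a per-trial response (e.g. bulk longitudinal
#' strain) on effort level (fraction of maximum voluntary contraction), with
#' subject as a fixed blocking factor when more than one subject is present.
#'
#' @param effort_level numeric vector of effort levels per trial.
#' @param response matching response values.
#' @param subject optional subject identifiers (blocking factor).
#' @return List with `slope`, `r_squared`, `p_value` (for the effort slope),
#'   and the fitted `model`.
#' @export
effort_regression <- function(effort_level, response, subject = NULL) {
  n <- length(effort_level)
  if (length(response) != n) stop("lengths differ")
  if (n < 3) stop("need at least 3 trials")
  dat <- data.frame(effort = effort_level, y = response)
  if (!is.null(subject) && length(unique(subject)) > 1) {
    dat$subject <- factor(subject)
    fit <- lm(y ~ effort + subject, data = dat)
  } else {
    fit <- lm(y ~ effort, data = dat)
  }
  sm <- summary(fit)
  slope <- unname(coef(fit)["effort"])
  pv <- sm$coefficients["effort", 4]
  r2 <- if (stats::sd(response) < 1e-12) 0 else sm$r.squared
  list(slope = slope, r_squared = r2, p_value = pv, model = fit)
}

#' Assemble a stress-strain record for one trial
#'
#' Converts a force trace plus per-frame bulk strain into a time-indexed
#' stress-strain record and fits the apparent modulus over the loading
#' phase.
#'
#' @param time frame times in seconds.
#' @param grip_force grip force in N per frame.
#' @param strain bulk longitudinal strain per frame.
#' @param csa tendon cross-sectional area in mm^2.
#' @param transmission see [tendon_force()].
#' @param loading_window time range of the loading (ramp) phase used for the
#'   modulus fit; default `c(0, 3)`.
#' @param window_fraction passed to [apparent_modulus()].
#' @return An object of class `stress_strain_record`.
#' @export
stress_strain_record <- function(time, grip_force, strain, csa,
                                 transmission = list(k = 0.25),
                                 loading_window = c(0, 3),
                                 window_fraction = 0.4) {
  if (length(time) != length(grip_force) || length(time) != length(strain))
    stop("time, grip_force and strain must have equal length")
  if (is.unsorted(time, strictly = TRUE)) stop("time must strictly increase")
  tf <- tendon_force(grip_force, transmission)
  sig <- stress(tf, csa)
  sel <- which(time >= loading_window[1] & time <= loading_window[2])
  mod <- apparent_modulus(sig[sel], strain[sel],
                          window_fraction = window_fraction)
  structure(list(time = time, tendon_force = tf, stress = sig,
                 bulk_strain = strain, csa = csa,
                 apparent_modulus = mod$modulus,
                 linear_region = sel[mod$linear_region],
                 r_squared = mod$r_squared),
            class = "stress_strain_record")
}
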