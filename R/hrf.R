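#' Canonical double-gamma hemodynamic response function
#'
#' The impulse response used to convolve stimulus boxcars into BOLD
#' regressors: a positive gamma density (peak near 5 s) minus a scaled,
#' later gamma density modeling the post-stimulus undershoot. Defaults are
#' the canonical parameterization (peak shape 6, undershoot shape 16, unit
#' rate scales, undershoot ratio 1/6). The curve is normalized to unit peak
#' so response amplitudes are expressed in signal units.
#'
#' @param peak_shape,undershoot_shape Gamma shape parameters (> 1 so that
#'   h(0) = 0).
#' @param peak_scale,undershoot_scale Gamma rate parameters (1/seconds).
#' @param undershoot_ratio Weight of the undershoot component.
#' @param dt Sampling step, seconds.
#' @param duration Support of the sampled curve, seconds.
#' @return An `hrf` object: list with `t` (time grid) and `values`.
#' @examples
#' h <- hrf_double_gamma()
#' h$t[which.max(h$values)] # close to the 5 s analytic mode
#' @export
hrf_double_gamma <- function(peak_shape = 6, undershoot_shape = 16,
                             peak_scale = 1, undershoot_scale = 1,
                             undershoot_ratio = 1 / 6,
                             dt = 1 / 16, duration = 32) {
  if (duration <= 0) abort("`duration` must be positive.")
  stopifnot(peak_shape > 0, undershoot_shape > 0,
            peak_scale > 0, undershoot_scale > 0)
  t <- seq(0, duration, by = dt)
  v <- dgamma(t, shape = peak_shape, rate = peak_scale) -
    undershoot_ratio * dgamma(t, shape = undershoot_shape,
                              rate = undershoot_scale)
  v <- v / max(v)
  structure(list(t = t, values = v, dt = dt, duration = duration,
                 params = list(peak_shape = peak_shape,
                               undershoot_shape = undershoot_shape,
                               peak_scale = peak_scale,
                               undershoot_scale = undershoot_scale,
                               undershoot_ratio = undershoot_ratio)),
            class = "hrf")
}

#' @export
print.hrf <- function(x, ...) {
  cat("<hrf> double-gamma, dt =", x$dt, "s, duration =", x$duration, "s\n")
  invisible(x)
}

# Convolve a set of boxcars with the HRF on an oversampled grid and decimate
# at volume acquisition times (t = 0, tr, 2 tr, ...). `onsets`/`durations`
# are parallel vectors; the result is the summed regressor.
convolve_boxcars <- function(onsets, durations, n_volumes, tr, hrf) {
  dt <- hrf$dt
  os <- round(tr / dt)
  if (abs(os * dt - tr) > 1e-9) {
    abort("`tr` must be a multiple of the HRF sampling step `dt`.")
  }
  n_fine <- n_volumes * os
  u <- numeric(n_fine + length(hrf$values))
  tfine <- (seq_len(n_fine) - 1L) * dt
  for (i in seq_along(onsets)) {
    if (durations[i] <= 0) next
    u_idx <- which(tfine >= onsets[i] & tfine < onsets[i] + durations[i])
    u[u_idx] <- u[u_idx] + 1
  }
  u <- u[seq_len(n_fine)]
  # Riemann approximation of the continuous convolution integral.
  conv <- dt * stats::convolve(u, rev(hrf$values), type = "open")
  conv[seq(1L, n_fine, by = os)]
}

#' Build an HRF-convolved regressor for one trial
#'
#' Convolves a boxcar of the given onset and duration with the HRF, sampled
#' internally on the HRF's fine grid and decimated at volume times.
#'
#' @param onset Trial onset in seconds from the start of the run (>= 0).
#' @param duration Trial duration in seconds (a zero duration yields an
#'   all-zero regressor).
#' @param n_volumes Number of volumes in the run.
#' @param tr Repetition time, seconds.
#' @param hrf An [hrf_double_gamma()] object.
#' @return Numeric vector of length `n_volumes`.
#' @export
build_trial_regressor <- function(onset, duration, n_volumes, tr,
                                  hrf = hrf_double_gamma()) {
  if (onset < 0) abort("`onset` must be non-negative.")
  if (onset > n_volumes * tr) {
    abort("`onset` lies beyond the end of the run.")
  }
  convolve_boxcars(onset, duration, n_volumes, tr, hrf)
}
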