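#' Spherical binary mask inside a volume
#'
#' @param shape Integer 3-vector of voxel counts.
#' @param center Voxel coordinate of the sphere center (1-based).
#' @param radius Radius in voxel units.
#' @return Logical 3D array.
#' @export
sphere_mask <- function(shape, center, radius) {
  stopifnot(length(shape) == 3, length(center) == 3, radius >= 0)
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  array(d2 <= radius^2, dim = shape)
}

#' Spatial activation patterns for a simulated study
#'
#' Describes where and how strongly each condition activates. Every trial of
#' any condition evokes a common, non-discriminative response of
#' `common_amplitude` across all voxels in the union of `regions`. Conditions
#' listed in `patterns` additionally evoke a condition-specific per-voxel
#' amplitude vector (scaled by `pattern_scale`) over one region's voxels —
#' this multivoxel pattern is what a decoder can pick up. Two conditions that
#' share one amplitude vector are indistinguishable by construction, which is
#' how the no-preference control pair is made to stay at chance.
#'
#' @param volume_shape Integer 3-vector of voxel counts.
#' @param regions Named list of logical 3D arrays (binary masks) within
#'   `volume_shape`.
#' @param patterns Named list (by condition) of lists `list(region =,
#'   values =)` where `values` has one amplitude per voxel of that region.
#' @param baseline Constant signal level added to every voxel.
#' @param pattern_scale Multiplier on all condition-specific patterns
#'   (the effect size dial; 0 removes all discriminative signal).
#' @param common_amplitude Amplitude of the shared stimulus response.
#' @return A `pattern_spec` list.
#' @export
pattern_spec <- function(volume_shape, regions = list(), patterns = list(),
                         baseline = 100, pattern_scale = 1,
                         common_amplitude = 1) {
  stopifnot(length(volume_shape) == 3, pattern_scale >= 0)
  for (nm in names(regions)) {
    if (!identical(dim(regions[[nm]]), as.integer(volume_shape))) {
      abort(paste0("Region '", nm, "' does not match `volume_shape`."))
    }
  }
  for (nm in names(patterns)) {
    p <- patterns[[nm]]
    if (!p$region %in% names(regions)) {
      abort(paste0("Pattern for '", nm, "' names unknown region '",
                   p$region, "'."))
    }
    if (length(p$values) != sum(regions[[p$region]])) {
      abort(paste0("Pattern for '", nm,
                   "' has the wrong number of voxel amplitudes."))
    }
  }
  structure(list(volume_shape = as.integer(volume_shape), regions = regions,
                 patterns = patterns, baseline = baseline,
                 pattern_scale = pattern_scale,
                 common_amplitude = common_amplitude),
            class = "pattern_spec")
}

#' Default study patterns: one active region, four discriminative conditions
#'
#' Builds the ground-truth spatial layout the acceptance analyses use: a
#' single spherical active region in which the four preference conditions
#' (H1, S1, H2, S2) each get an independent Gaussian amplitude vector while
#' the two no-preference conditions (H3, S3) share one vector, so a 4-way
#' preference decoder can succeed but the 2-way H3-vs-S3 control cannot.
#'
#' @param volume_shape Integer 3-vector.
#' @param center,radius Location/size of the active region (voxel units).
#' @param pattern_scale Effect size multiplier (see [pattern_spec()]).
#' @param seed Integer seed for the amplitude vectors.
#' @inheritParams pattern_spec
#' @return A `pattern_spec`.
#' @export
default_study_patterns <- function(volume_shape = c(12, 12, 12),
                                   center = c(6, 6, 6), radius = 4,
                                   pattern_scale = 1, baseline = 100,
                                   common_amplitude = 1, seed = 1L) {
  region <- sphere_mask(volume_shape, center, radius)
  nvox <- sum(region)
  vals <- with_seed(derive_seed(seed, "patterns"), {
    v <- purrr::map(1:5, ~ rnorm(nvox))
    names(v) <- c("H1", "S1", "H2", "S2", "NOPREF")
    v
  })
  patterns <- list(
    H1 = list(region = "active", values = vals$H1),
    S1 = list(region = "active", values = vals$S1),
    H2 = list(region = "active", values = vals$H2),
    S2 = list(region = "active", values = vals$S2),
    H3 = list(region = "active", values = vals$NOPREF),
    S3 = list(region = "active", values = vals$NOPREF)
  )
  pattern_spec(volume_shape, regions = list(active = region),
               patterns = patterns, baseline = baseline,
               pattern_scale = pattern_scale,
               common_amplitude = common_amplitude)
}

#' Noise model for simulated BOLD
#'
#' @param sigma Marginal standard deviation of the AR(1) Gaussian noise.
#' @param ar1_coef Lag-1 autocorrelation, in `[0, 1)`.
#' @param drift_amplitude Scale of the low-frequency cosine drift.
#' @param motion_leak Coupling of the motion series into voxel signals.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(sigma = 1, ar1_coef = 0.3, drift_amplitude = 0.5,
                       motion_leak = 0.1) {
  stopifnot(sigma >= 0, ar1_coef >= 0, ar1_coef < 1)
  structure(list(sigma = sigma, ar1_coef = ar1_coef,
                 drift_amplitude = drift_amplitude,
                 motion_leak = motion_leak),
            class = "noise_spec")
}

#' Simulate smooth head-motion parameter series
#'
#' A smoothed Gaussian random walk for each of the six rigid-body parameters
#' (3 translations, 3 rotations), centered to zero mean per column.
#'
#' @param n_volumes Number of volumes (>= 1).
#' @param seed Integer seed.
#' @param step_sd Random-walk innovation standard deviation.
#' @return `n_volumes` x 6 numeric matrix, columns
#'   `trans_x, trans_y, trans_z, rot_x, rot_y, rot_z`.
#' @export
simulate_motion <- function(n_volumes, seed = 1L, step_sd = 0.02) {
  stopifnot(n_volumes >= 1)
  with_seed(derive_seed(seed, "motion"), {
    m <- apply(matrix(rnorm(n_volumes * 6, sd = step_sd), n_volumes, 6),
               2, cumsum)
    m <- matrix(m, nrow = n_volumes)
    # light smoothing, then exact per-column centering
    if (n_volumes >= 5) {
      k <- rep(1 / 5, 5)
      m <- apply(m, 2, function(col) {
        sm <- stats::filter(col, k, sides = 2)
        sm[is.na(sm)] <- col[is.na(sm)]
        as.numeric(sm)
      })
      m <- matrix(m, nrow = n_volumes)
    }
    m <- sweep(m, 2, colMeans(m))
    colnames(m) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
    m
  })
}

#' Simulate a 4D BOLD run
#'
#' Forward model: each voxel's time course is
#' `baseline + sum over conditions of amplitude(condition, voxel) *`
#' HRF-convolved condition boxcar `+ drift + motion_leak * motion +`
#' AR(1) Gaussian noise, where `amplitude = common_amplitude` over the active
#' regions plus `pattern_scale *` the condition's pattern values.
#'
#' @param events Event table for a single run.
#' @param patterns A [pattern_spec()].
#' @param noise A [noise_spec()].
#' @param motion Motion parameter matrix (rows = volumes) from
#'   [simulate_motion()]; its row count fixes the run length.
#' @param tr Repetition time, seconds.
#' @param hrf HRF used to convolve the boxcars.
#' @param seed Integer seed.
#' @return 4D array `x * y * z * volumes`.
#' @export
simulate_bold <- function(events, patterns, noise, motion, tr = 1,
                          hrf = hrf_double_gamma(), seed = 1L) {
  stopifnot(inherits(patterns, "pattern_spec"), inherits(noise, "noise_spec"))
  n_vol <- nrow(motion)
  if (max(events$onset + events$duration) > n_vol * tr) {
    abort("Events extend beyond the simulated run length.")
  }
  shape <- patterns$volume_shape
  n_vox <- prod(shape)

  # condition-wise convolved regressors (T x C)
  conds <- sort(unique(events$condition))
  X <- vapply(conds, function(cc) {
    ee <- events[events$condition == cc, ]
    convolve_boxcars(ee$onset, ee$duration, n_vol, tr, hrf)
  }, numeric(n_vol))

  # amplitude matrix (C x V)
  amp <- matrix(0, length(conds), n_vox)
  active <- logical(n_vox)
  for (rg in patterns$regions) active <- active | as.vector(rg)
  amp[, active] <- patterns$common_amplitude
  for (cc in names(patterns$patterns)) {
    i <- match(cc, conds)
    if (is.na(i)) next
    p <- patterns$patterns[[cc]]
    vox <- which(as.vector(patterns$regions[[p$region]]))
    amp[i, vox] <- amp[i, vox] + patterns$pattern_scale * p$values
  }
  signal <- X %*% amp # T x V

  with_seed(derive_seed(seed, "bold"), {
    if (noise$drift_amplitude != 0) {
      t01 <- (seq_len(n_vol) - 1) / max(n_vol - 1, 1)
      basis <- cbind(cos(pi * t01), cos(2 * pi * t01), cos(3 * pi * t01))
      w <- matrix(rnorm(3 * n_vox), 3, n_vox)
      signal <- signal + noise$drift_amplitude * (basis %*% w)
    }
    if (noise$motion_leak != 0) {
      w <- matrix(rnorm(6 * n_vox), 6, n_vox)
      signal <- signal + noise$motion_leak * (motion %*% w)
    }
    if (noise$sigma > 0) {
      innov_sd <- noise$sigma * sqrt(1 - noise$ar1_coef^2)
      e <- matrix(rnorm(n_vol * n_vox, sd = innov_sd), n_vol, n_vox)
      if (noise$ar1_coef > 0) {
        e <- stats::filter(e, noise$ar1_coef, method = "recursive")
        e <- matrix(as.numeric(e), n_vol, n_vox)
      }
      signal <- signal + e
    }
    signal <- signal + patterns$baseline
    array(t(signal), dim = c(shape, n_vol))
  })
}

#' Simulate one subject's complete dataset
#'
#' Convenience wrapper chaining [generate_design()], [simulate_behavior()],
#' [simulate_motion()] and [simulate_bold()] for all runs of one subject.
#'
#' @param design A [design_spec()] (its `seed` is combined with `subject`).
#' @param patterns A [pattern_spec()].
#' @param noise A [noise_spec()].
#' @param subject Subject index used to decorrelate seeds across subjects.
#' @param p_correct,p_respond Behavioral response probabilities.
#' @param hrf HRF for the forward model.
#' @param seed Global seed.
#' @return List with `events` (tibble over all runs), `motion` (list of
#'   matrices), `bold` (list of 4D arrays), `n_volumes`, and the specs used.
#' @export
simulate_subject <- function(design, patterns, noise, subject = 1L,
                             p_correct = 0.94, p_respond = 0.98,
                             hrf = hrf_double_gamma(), seed = 1L) {
  dseed <- derive_seed(seed, "subject", subject)
  des <- design
  des$seed <- dseed
  events <- generate_design(des)
  events <- simulate_behavior(events, p_correct, p_respond, seed = dseed)
  n_vol <- run_n_volumes(events, des)
  runs <- sort(unique(events$run))
  motion <- purrr::map(runs, ~ simulate_motion(n_vol,
                                               seed = derive_seed(dseed, "m", .x)))
  bold <- purrr::map(runs, function(r) {
    simulate_bold(events[events$run == r, ], patterns, noise,
                  motion[[r + 1L]], tr = des$tr, hrf = hrf,
                  seed = derive_seed(dseed, "b", r))
  })
  list(events = events, motion = motion, bold = bold, n_volumes = n_vol,
       design = des, patterns = patterns, noise = noise, subject = subject)
}
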