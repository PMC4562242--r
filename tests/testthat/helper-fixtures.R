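# Shared fixture builders: everything is generated in code at test time.

# Beta series with class-separated Gaussian samples, balanced across runs.
# `sep` is the distance between class means; sep = 0 gives pure noise.
make_class_betas <- function(n_runs = 4, per_class = 4,
                             classes = c("H1", "S1", "H2", "S2"),
                             n_vox = 30, sep = 5, noise_sd = 1, seed = 1) {
  set.seed(seed)
  k <- length(classes)
  centers <- matrix(rnorm(k * n_vox), k, n_vox) * sep
  rows <- list()
  data <- NULL
  for (r in seq_len(n_runs) - 1L) {
    cond <- sample(rep(classes, per_class))
    x <- centers[match(cond, classes), , drop = FALSE] +
      matrix(rnorm(length(cond) * n_vox, sd = noise_sd), length(cond), n_vox)
    data <- rbind(data, x)
    rows[[r + 1L]] <- tibble::tibble(condition = cond, run = r,
                                    correct = TRUE, responded = TRUE)
  }
  beta_series(data, dplyr::bind_rows(rows))
}

# Attach voxel coordinates so a beta series can feed the searchlight.
with_voxel_grid <- function(bs, dims) {
  stopifnot(ncol(bs$data) == prod(dims))
  bs$voxels <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                                     seq_len(dims[3])))
  storage.mode(bs$voxels) <- "integer"
  colnames(bs$voxels) <- NULL
  bs$dim <- as.integer(dims)
  bs
}

# A tiny fully simulated subject (fast; used by LSS and pipeline tests).
make_tiny_subject <- function(n_runs = 2, shape = c(6, 6, 6),
                              pattern_scale = 1, sigma = 0.5, seed = 3,
                              trials_per_condition = 2,
                              conditions = c("H1", "S1", "H2", "S2"),
                              isi_min = 4, isi_max = 10) {
  design <- design_spec(n_runs = n_runs, conditions = conditions,
                        trials_per_condition = trials_per_condition,
                        isi_min = isi_min, isi_max = isi_max,
                        seed = seed)
  patterns <- default_study_patterns(volume_shape = shape,
                                     center = ceiling(shape / 2), radius = 2,
                                     pattern_scale = pattern_scale,
                                     seed = seed)
  simulate_subject(design, patterns,
                   noise_spec(sigma = sigma, drift_amplitude = 0,
                              motion_leak = 0),
                   p_correct = 1, p_respond = 1, seed = seed)
}

# Independent direct-summation convolution oracle on the HRF's fine grid.
direct_conv_oracle <- function(onset, duration, n_volumes, tr, hrf) {
  dt <- hrf$dt
  n_fine <- round(n_volumes * tr / dt)
  tfine <- (seq_len(n_fine) - 1) * dt
  u <- as.numeric(tfine >= onset & tfine < onset + duration)
  hv <- hrf$values
  out <- numeric(n_volumes)
  for (v in seq_len(n_volumes)) {
    tv <- (v - 1) * tr
    # r(tv) = dt * sum_j u(t_j) h(tv - t_j)
    lag <- round((tv - tfine) / dt) + 1L
    ok <- lag >= 1 & lag <= length(hv) & u > 0
    out[v] <- dt * sum(u[ok] * hv[lag[ok]])
  }
  out
}
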