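#' Construct a beta series
#'
#' A beta series is the decoding substrate: one multivoxel sample per trial.
#' `data` holds the trial-wise amplitude estimates (samples x voxels) and
#' `labels` the per-sample metadata (`condition`, `run`, `correct`,
#' `responded`, in trial order within run, runs concatenated in run order).
#' `voxels` records which voxel each column came from (coordinates within
#' `dim`), so samples can be mapped back into the volume for searchlights.
#'
#' @param data Numeric matrix, samples x voxels.
#' @param labels Tibble with one row per sample.
#' @param voxels Integer matrix (voxels x 3) of 1-based coordinates, or NULL.
#' @param dim Integer 3-vector, the originating volume shape, or NULL.
#' @return A `beta_series` object.
#' @export
beta_series <- function(data, labels, voxels = NULL, dim = NULL) {
  stopifnot(is.matrix(data), nrow(data) == nrow(labels))
  if (!is.null(voxels)) stopifnot(nrow(voxels) == ncol(data))
  structure(list(data = data, labels = tibble::as_tibble(labels),
                 voxels = voxels, dim = dim),
            class = "beta_series")
}

#' @export
print.beta_series <- function(x, ...) {
  cat("<beta_series> ", nrow(x$data), " samples x ", ncol(x$data),
      " voxels, ", length(unique(x$labels$run)), " run(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.beta_series <- function(x) dim(x$data)

# Convolved regressor for every trial of a run, plus nuisance columns.
# Returns list(trial = T x n_trials matrix, nuisance = T x q matrix).
run_design_columns <- function(events, n_volumes, tr, hrf, motion,
                               drift = NULL, intercept = TRUE) {
  trial <- vapply(seq_len(nrow(events)), function(i) {
    build_trial_regressor(events$onset[i], events$duration[i],
                          n_volumes, tr, hrf)
  }, numeric(n_volumes))
  nuis <- motion
  if (intercept) nuis <- cbind(nuis, intercept = 1)
  if (!is.null(drift)) nuis <- cbind(nuis, drift)
  if (ncol(nuis) == 0) {
    abort("The nuisance block is empty; include an intercept or motion.")
  }
  list(trial = trial, nuisance = nuis)
}

#' Trial-wise amplitude estimation by least-squares-separate (LSS)
#'
#' Fits, for each trial, an ordinary-least-squares model whose design holds
#' the target trial's HRF-convolved regressor, a single regressor collapsing
#' all other trials, the six motion parameters and a run intercept; the
#' target-trial coefficient is kept for every in-mask voxel. This per-trial
#' two-regressor scheme reduces the collinearity that plagues per-trial
#' estimates in fast event-related designs.
#'
#' The fit is computed from per-run cross-products, which is algebraically
#' identical to solving each trial's normal equations separately.
#'
#' @param bold 4D array for one run (`x, y, z, volumes`).
#' @param events Event table for that run (>= 2 trials).
#' @param motion Volumes x 6 motion matrix for that run.
#' @param mask Logical 3D array selecting the voxels to estimate.
#' @param tr Repetition time, seconds.
#' @param hrf HRF used to build regressors.
#' @param drift Optional volumes x q matrix of extra nuisance columns
#'   (e.g. a cosine drift set).
#' @param intercept Include a run intercept among the nuisance columns
#'   (default TRUE).
#' @return A [beta_series()] for the run.
#' @export
estimate_betas_lss <- function(bold, events, motion, mask, tr = 1,
                               hrf = hrf_double_gamma(), drift = NULL,
                               intercept = TRUE) {
  stopifnot(length(dim(bold)) == 4)
  if (!any(mask)) abort("`mask` selects no voxels.")
  n_trials <- nrow(events)
  if (n_trials < 2) abort("LSS needs at least 2 trials per run.")
  n_vol <- dim(bold)[4]
  if (is.null(motion)) motion <- matrix(numeric(0), n_vol, 0)
  stopifnot(nrow(motion) == n_vol)

  cols <- run_design_columns(events, n_vol, tr, hrf, motion, drift,
                             intercept = intercept)
  R <- cbind(cols$trial, cols$nuisance) # T x (n_trials + q)
  q <- ncol(cols$nuisance)

  # rank check on the stacked single-trial design (trial columns may be
  # collinear with each other without harming LSS, but nuisance columns and
  # each trial-vs-rest pair must be independent)
  vox <- which(mask)
  Y <- t(matrix(bold, prod(dim(bold)[1:3]), n_vol))[, vox, drop = FALSE]

  G <- crossprod(R)        # (n+q) x (n+q)
  C <- crossprod(R, Y)     # (n+q) x V
  tot <- seq_len(n_trials)
  nuis_idx <- n_trials + seq_len(q)

  betas <- matrix(NA_real_, n_trials, length(vox))
  I_nuis <- diag(n_trials + q)[, nuis_idx, drop = FALSE]
  for (t in tot) {
    # design for trial t: [target, others, nuisance]; others = sum - target,
    # expressed as a linear recombination E of the stacked columns
    e_t <- numeric(n_trials + q); e_t[t] <- 1
    e_o <- numeric(n_trials + q); e_o[tot] <- 1; e_o[t] <- 0
    E <- cbind(e_t, e_o, I_nuis)
    Gt <- crossprod(E, G %*% E)
    Ct <- crossprod(E, C)
    if (qr(Gt)$rank < ncol(Gt)) {
      abort(paste0("Rank-deficient LSS design for trial ", t,
                   ": collinearity among [target, other-trials, nuisance] ",
                   "columns."),
            class = "decodelight_rank_deficient")
    }
    coef <- solve(Gt, Ct)
    betas[t, ] <- coef[1, ]
  }

  labels <- tibble::tibble(
    condition = events$condition,
    run = events$run,
    trial = events$trial %||% (seq_len(n_trials) - 1L),
    correct = events$correct,
    responded = events$responded
  )
  coords <- which(mask, arr.ind = TRUE)
  beta_series(betas, labels, voxels = coords, dim = dim(bold)[1:3])
}

#' Concatenate per-run beta series
#'
#' Row-stacks the samples of several runs (in the order given), preserving
#' labels; all runs must share the voxel set.
#'
#' @param per_run List of [beta_series()] objects.
#' @return A single [beta_series()].
#' @export
concatenate_beta_series <- function(per_run) {
  stopifnot(length(per_run) >= 1)
  nv <- vapply(per_run, function(b) ncol(b$data), integer(1))
  if (length(unique(nv)) != 1) {
    abort("Voxel counts differ across runs; cannot concatenate.")
  }
  beta_series(
    do.call(rbind, lapply(per_run, `[[`, "data")),
    dplyr::bind_rows(lapply(per_run, `[[`, "labels")),
    voxels = per_run[[1]]$voxels,
    dim = per_run[[1]]$dim
  )
}

#' Estimate a subject's full beta series
#'
#' Runs [estimate_betas_lss()] on every run of a simulated (or loaded)
#' subject dataset and concatenates the per-run series.
#'
#' @param subject A list as returned by [simulate_subject()].
#' @param mask Logical 3D mask; defaults to all voxels.
#' @param hrf HRF used to build regressors.
#' @param drift Optional nuisance columns shared across runs.
#' @return A [beta_series()] spanning all runs.
#' @export
subject_beta_series <- function(subject, mask = NULL,
                                hrf = hrf_double_gamma(), drift = NULL) {
  shape <- dim(subject$bold[[1]])[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = shape)
  runs <- sort(unique(subject$events$run))
  per_run <- purrr::map(runs, function(r) {
    estimate_betas_lss(subject$bold[[r + 1L]],
                       subject$events[subject$events$run == r, ],
                       subject$motion[[r + 1L]], mask,
                       tr = subject$design$tr, hrf = hrf, drift = drift)
  })
  concatenate_beta_series(per_run)
}

#' Write / read a beta series as NIfTI + sidecar label TSV
#'
#' The series is written as a 4D volume with one volume per trial (voxels
#' outside the series' voxel set are zero) plus a tab-separated sidecar of
#' per-sample labels.
#'
#' @param bs A [beta_series()] carrying voxel coordinates and volume shape.
#' @param path Output NIfTI path; the sidecar is `path` with `.tsv` extension.
#' @return `write_beta_series` returns `path` invisibly; `read_beta_series`
#'   returns a [beta_series()] restricted to `mask` (default: voxels that are
#'   nonzero in any volume).
#' @export
write_beta_series <- function(bs, path) {
  stopifnot(!is.null(bs$voxels), !is.null(bs$dim))
  n <- nrow(bs$data)
  vol <- array(0, dim = c(bs$dim, n))
  flat <- bs$voxels[, 1] + (bs$voxels[, 2] - 1L) * bs$dim[1] +
    (bs$voxels[, 3] - 1L) * bs$dim[1] * bs$dim[2]
  for (i in seq_len(n)) {
    v <- array(0, dim = bs$dim)
    v[flat] <- bs$data[i, ]
    vol[, , , i] <- v
  }
  write_volume(vol, path)
  readr::write_tsv(bs$labels, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".tsv", path)
}

#' @rdname write_beta_series
#' @param mask Logical 3D array restricting voxels on read.
#' @export
read_beta_series <- function(path, mask = NULL) {
  vol <- read_volume(path)
  labels <- readr::read_tsv(sidecar_path(path), show_col_types = FALSE,
                            progress = FALSE)
  shape <- dim(vol)[1:3]
  flatmat <- matrix(vol, prod(shape), dim(vol)[4])
  if (is.null(mask)) {
    keep <- rowSums(flatmat != 0) > 0
  } else {
    keep <- as.vector(mask)
  }
  coords <- which(array(keep, dim = shape), arr.ind = TRUE)
  beta_series(t(flatmat[keep, , drop = FALSE]), labels,
              voxels = coords, dim = shape)
}
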