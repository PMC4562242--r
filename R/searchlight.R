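#' Integer offsets of a spherical searchlight
#'
#' All integer voxel offsets `(dx, dy, dz)` with squared Euclidean norm at
#' most `radius^2`, in isotropic voxel units. A radius of 3 yields the
#' classic 123-voxel searchlight.
#'
#' @param radius Sphere radius in voxel units (>= 0).
#' @return Integer matrix (offsets x 3), including the center `(0,0,0)` and
#'   symmetric under negation.
#' @examples
#' nrow(sphere_offsets(3)) # 123
#' @export
sphere_offsets <- function(radius) {
  if (radius < 0) abort("`radius` must be non-negative.")
  r <- floor(radius)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  keep <- rowSums(g^2) <= radius^2
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

#' Searchlight decoding map
#'
#' Moves a spherical searchlight over every in-mask voxel; at each center the
#' in-mask voxels within the sphere are decoded with the same Gaussian naive
#' Bayes leave-one-run-out procedure as the ROI analysis (per-sample
#' z-scoring within the sphere's voxels, training-set balancing, no feature
#' selection) and the accuracy is assigned to the center voxel. Optionally
#' the same spheres are decoded under `n_perm` within-run label permutations,
#' yielding per-permutation chance accuracy maps in the same pass.
#'
#' Centers whose sphere contains fewer than 2 usable voxels are left
#' undefined (`NA`). Results are independent of the order in which centers
#' are visited: balancing draws are keyed on (seed, center, fold, label set).
#'
#' @param betas A [beta_series()] with voxel coordinates and volume shape.
#' @param mask Logical 3D array of centers/voxels to use; default: every
#'   voxel present in the series.
#' @param radius Sphere radius in voxel units.
#' @param targets Conditions or condition-to-class mapping
#'   (see [crossvalidate_loro()]).
#' @param n_perm Number of within-run label permutations to decode alongside
#'   the true labels.
#' @param seed Integer seed for balancing and permutations.
#' @param engine `"cpp"` (compiled, default) or `"R"` (reference
#'   implementation; identical results whenever training folds are balanced).
#' @return A `searchlight_result`: list with `accuracy` (3D array, NA outside
#'   the mask), `counts` (3D array of per-center sphere sizes), `chance`
#'   (n_perm x centers matrix of chance accuracies), `confusion`
#'   (centers x K x K array of true-label fold-pooled counts), `centers`
#'   (centers x 3 coordinates), `classes`, `dim`.
#' @export
run_searchlight <- function(betas, mask = NULL, radius = 3, targets,
                            n_perm = 0, seed = 1L,
                            engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  stopifnot(!is.null(betas$voxels), !is.null(betas$dim))
  dims <- betas$dim
  voxcol <- integer(prod(dims))
  flat <- betas$voxels[, 1] + (betas$voxels[, 2] - 1L) * dims[1] +
    (betas$voxels[, 3] - 1L) * dims[1] * dims[2]
  voxcol[flat] <- seq_len(ncol(betas$data))
  if (is.null(mask)) {
    mask <- array(FALSE, dims)
    mask[flat] <- TRUE
  } else {
    # restrict data to in-mask voxels so spheres only gather mask voxels
    voxcol[!as.vector(mask)] <- 0L
  }
  center_flat <- which(as.vector(mask) & voxcol > 0L)
  if (length(center_flat) == 0) abort("`mask` selects no data voxels.")
  centers <- arrayInd(center_flat, dims)
  storage.mode(centers) <- "integer"

  map <- target_class_map(targets)
  classes <- unique(unname(map))
  k <- length(classes)
  labels <- betas$labels
  eligible <- labels$correct & labels$condition %in% names(map)
  cls_id <- integer(nrow(labels))
  cls_id[eligible] <- match(unname(map[labels$condition[eligible]]), classes)
  run <- as.integer(labels$run)

  lab_mat <- matrix(0L, nrow(labels), n_perm + 1L)
  lab_mat[, 1] <- cls_id
  if (n_perm > 0) {
    for (p in seq_len(n_perm)) {
      perm <- cls_id
      perm[eligible] <- permute_labels_within_runs(
        cls_id[eligible], run[eligible],
        seed = derive_seed(seed, "perm", p))
      lab_mat[, p + 1L] <- perm
    }
  }

  off <- sphere_offsets(radius)
  if (engine == "cpp") {
    res <- .searchlight_engine(betas$data, voxcol, centers, off,
                               as.integer(dims), run, lab_mat, k,
                               1e-9, as.double(seed %% 2^31), TRUE)
  } else {
    res <- searchlight_engine_r(betas$data, voxcol, centers, off, dims, run,
                                lab_mat, k, seed)
  }
  acc_map <- array(NA_real_, dims)
  acc_map[center_flat] <- res$accuracy[, 1]
  count_map <- array(NA_real_, dims)
  count_map[center_flat] <- res$counts
  chance <- if (n_perm > 0) t(res$accuracy[, -1, drop = FALSE]) else
    matrix(numeric(0), 0, length(center_flat))
  confusion <- array(res$confusion, dim = c(length(center_flat), k, k))
  structure(list(accuracy = acc_map, counts = count_map, chance = chance,
                 confusion = confusion, centers = centers,
                 center_flat = center_flat, classes = classes, dim = dims),
            class = "searchlight_result")
}

# Reference R implementation of the compiled engine; shares the same
# decoding path and the keep-all-when-balanced rule.
searchlight_engine_r <- function(data, voxcol, centers, off, dims, run,
                                 lab_mat, k, seed) {
  m <- nrow(centers)
  n_maps <- ncol(lab_mat)
  acc <- matrix(NA_real_, m, n_maps)
  counts <- integer(m)
  confusion <- matrix(0, m, k * k)
  elig <- which(lab_mat[, 1] > 0L)
  uruns <- sort(unique(run[elig]))
  for (c in seq_len(m)) {
    coords <- sweep(off, 2, unlist(centers[c, ]), "+")
    inside <- coords[, 1] >= 1 & coords[, 1] <= dims[1] &
      coords[, 2] >= 1 & coords[, 2] <= dims[2] &
      coords[, 3] >= 1 & coords[, 3] <= dims[3]
    coords <- coords[inside, , drop = FALSE]
    fl <- coords[, 1] + (coords[, 2] - 1L) * dims[1] +
      (coords[, 3] - 1L) * dims[1] * dims[2]
    colsel <- voxcol[fl]
    colsel <- colsel[colsel > 0L]
    counts[c] <- length(colsel)
    if (length(colsel) < 2) next
    Z <- znorm_samples(data[elig, colsel, drop = FALSE])
    correct <- numeric(n_maps)
    total <- numeric(n_maps)
    for (fi in seq_along(uruns)) {
      r <- uruns[fi]
      tr <- which(run[elig] != r)
      te <- which(run[elig] == r)
      if (length(te) == 0 || length(tr) == 0) next
      for (mm in seq_len(n_maps)) {
        cl_tr <- factor(lab_mat[elig[tr], mm], levels = seq_len(k))
        bal <- balance_training_set(cl_tr,
                                    seed = derive_seed(seed, "sl", c, fi, mm))
        idx <- tr[bal]
        model <- gnb_fit(Z[idx, , drop = FALSE],
                         factor(lab_mat[elig[idx], mm], levels = seq_len(k)))
        pred <- as.integer(gnb_predict(model, Z[te, , drop = FALSE]))
        actual <- lab_mat[elig[te], mm]
        total[mm] <- total[mm] + length(te)
        correct[mm] <- correct[mm] + sum(pred == actual)
        if (mm == 1) {
          for (i in seq_along(te)) {
            cell <- actual[i] + (pred[i] - 1L) * k
            confusion[c, cell] <- confusion[c, cell] + 1
          }
        }
      }
    }
    acc[c, ] <- ifelse(total > 0, correct / total, NA_real_)
  }
  list(accuracy = acc, counts = counts, confusion = confusion)
}

#' @export
print.searchlight_result <- function(x, ...) {
  ok <- !is.na(x$accuracy)
  cat("<searchlight_result> ", sum(ok), " centers, ",
      length(x$classes), "-way, mean accuracy ",
      sprintf("%.3f", mean(x$accuracy[ok])), ", ",
      nrow(x$chance), " permutation map(s)\n", sep = "")
  invisible(x)
}

#' Average scaled confusion matrix over a cluster of searchlight centers
#'
#' Element-wise mean of the row-scaled (percentage) confusion matrices of all
#' searchlight centers in a cluster; rows of the result still sum to 100 (up
#' to rounding).
#'
#' @param cluster_voxels Integer vector of flat voxel indices (or an
#'   n x 3 coordinate matrix) of the cluster's centers.
#' @param sl A `searchlight_result` holding per-center confusion matrices.
#' @return K x K numeric matrix of mean percentages.
#' @export
cluster_confusion <- function(cluster_voxels, sl) {
  if (is.matrix(cluster_voxels)) {
    cluster_voxels <- cluster_voxels[, 1] +
      (cluster_voxels[, 2] - 1L) * sl$dim[1] +
      (cluster_voxels[, 3] - 1L) * sl$dim[1] * sl$dim[2]
  }
  if (length(cluster_voxels) == 0) abort("Empty cluster.")
  rows <- match(cluster_voxels, sl$center_flat)
  if (anyNA(rows)) {
    abort("Some cluster voxels have no stored searchlight confusion matrix.")
  }
  k <- length(sl$classes)
  acc <- matrix(0, k, k)
  for (r in rows) {
    acc <- acc + scale_confusion(matrix(sl$confusion[r, , ], k, k))
  }
  out <- acc / length(rows)
  dimnames(out) <- list(actual = sl$classes, predicted = sl$classes)
  out
}
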