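#' Permute labels independently within each run
#'
#' Shuffles the label vector within every run, preserving each run's label
#' multiset — the exchangeability unit for run-wise cross-validated decoding.
#'
#' @param labels Vector of labels.
#' @param runs Run index per label (same length).
#' @param seed Integer seed.
#' @return Permuted label vector.
#' @export
permute_labels_within_runs <- function(labels, runs, seed = 1L) {
  stopifnot(length(labels) == length(runs))
  out <- labels
  with_seed(derive_seed(seed, "permute"), {
    for (r in unique(runs)) {
      ix <- which(runs == r)
      if (length(ix) > 1) out[ix] <- labels[ix[sample.int(length(ix))]]
    }
  })
  out
}

#' Bootstrap a group-level null distribution from per-subject chance values
#'
#' Each bootstrap draw picks, with replacement, one chance accuracy (or one
#' chance accuracy map) per subject and averages across subjects. Repeated
#' `n_boot` times this yields the group-level null distribution of the mean
#' accuracy (or, voxelwise, of the mean accuracy map).
#'
#' @param chance List with one element per subject: a numeric vector of
#'   chance accuracies, or a matrix (permutations x voxels) of chance maps.
#' @param n_boot Number of bootstrap draws (>= 1).
#' @param seed Integer seed.
#' @return For vector input, a sorted numeric vector of length `n_boot`; for
#'   matrix input, an `n_boot x voxels` matrix (rows unsorted).
#' @export
bootstrap_group_null <- function(chance, n_boot, seed = 1L) {
  stopifnot(length(chance) >= 1, n_boot >= 1)
  if (any(lengths(chance) == 0)) abort("Empty chance set for some subject.")
  n_sub <- length(chance)
  is_map <- is.matrix(chance[[1]])
  with_seed(derive_seed(seed, "bootstrap"), {
    if (!is_map) {
      draws <- vapply(chance, function(v) {
        v[sample.int(length(v), n_boot, replace = TRUE)]
      }, numeric(n_boot))
      sort(rowMeans(matrix(draws, n_boot, n_sub)))
    } else {
      nv <- ncol(chance[[1]])
      acc <- matrix(0, n_boot, nv)
      for (s in seq_len(n_sub)) {
        idx <- sample.int(nrow(chance[[s]]), n_boot, replace = TRUE)
        acc <- acc + chance[[s]][idx, , drop = FALSE]
      }
      acc / n_sub
    }
  })
}

#' One-sided empirical p-value with the add-one estimator
#'
#' `p = (1 + #\{null >= observed\}) / (1 + n_draws)`: the observed statistic is
#' treated as one more draw from the null, so p can never be exactly zero.
#'
#' @param observed Observed statistic (scalar, or vector for voxelwise maps).
#' @param null Numeric vector of null draws, or a matrix with one column per
#'   element of `observed`.
#' @return Empirical p-value(s) in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null) {
  if (is.matrix(null)) {
    stopifnot(length(observed) == ncol(null))
    cnt <- colSums(null >= matrix(observed, nrow(null), ncol(null),
                                  byrow = TRUE))
    (1 + cnt) / (1 + nrow(null))
  } else {
    if (length(null) == 0) abort("Empty null distribution.")
    vapply(observed, function(o) (1 + sum(null >= o)) / (1 + length(null)),
           numeric(1))
  }
}

#' Voxelwise threshold of a group accuracy map
#'
#' Retains a voxel iff its add-one empirical p-value against the voxelwise
#' bootstrap null is strictly below `alpha`.
#'
#' @param observed Numeric vector of group accuracies over mask voxels.
#' @param null_maps Bootstrap null matrix (`draws x voxels`), same voxel
#'   order.
#' @param alpha Voxelwise significance level.
#' @return Logical vector over the mask voxels.
#' @export
threshold_map <- function(observed, null_maps, alpha = 0.001) {
  if (length(observed) != ncol(null_maps)) {
    abort("Observed map and null maps are on different grids.")
  }
  empirical_pvalue(observed, null_maps) < alpha
}

# 3D connected components by breadth-first flood over an offset
# neighborhood; `connectivity` 6 (faces) or 26 (faces+edges+corners).
neighbor_offsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  else if (connectivity != 26) abort("`connectivity` must be 6 or 26.")
  g
}

#' Connected clusters of a binary 3D map
#'
#' Labels connected components of the supra-threshold voxels under 6- or
#' 26-neighbor connectivity.
#'
#' @param binary Logical 3D array.
#' @param connectivity 6 or 26.
#' @return List with `labels` (integer 3D array, 0 = background) and `table`
#'   (tibble: `cluster`, `size`).
#' @export
find_clusters <- function(binary, connectivity = 26) {
  dims <- dim(binary)
  stopifnot(length(dims) == 3)
  off <- neighbor_offsets(connectivity)
  off_flat <- off[, 1] + off[, 2] * dims[1] + off[, 3] * dims[1] * dims[2]
  lab <- array(0L, dims)
  supra <- which(binary)
  coords <- arrayInd(supra, dims)
  in_vol <- array(FALSE, dims)
  in_vol[supra] <- TRUE
  cur <- 0L
  sizes <- integer(0)
  for (i in seq_along(supra)) {
    v <- supra[i]
    if (lab[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    lab[v] <- cur
    size <- 0L
    while (length(queue) > 0) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      size <- size + 1L
      qc <- arrayInd(q, dims)[1, ]
      nb_ok <- off[, 1] + qc[1] >= 1 & off[, 1] + qc[1] <= dims[1] &
        off[, 2] + qc[2] >= 1 & off[, 2] + qc[2] <= dims[2] &
        off[, 3] + qc[3] >= 1 & off[, 3] + qc[3] <= dims[3]
      nb <- q + off_flat[nb_ok]
      nb <- nb[in_vol[nb] & lab[nb] == 0L]
      if (length(nb) > 0) {
        lab[nb] <- cur
        queue <- c(queue, nb)
      }
    }
    sizes <- c(sizes, size)
  }
  list(labels = lab,
       table = tibble::tibble(cluster = seq_len(cur), size = sizes))
}

#' Threshold bootstrap chance maps against their own null
#'
#' Applies the voxelwise threshold to each bootstrap group chance map using
#' the same add-one estimator as the observed map, with the tested map
#' standing in as the "+1" pseudo-draw of its own formula:
#' `p_j(v) = (1 + #\{k != j: null_k(v) >= null_j(v)\}) / (1 + n_draws)`.
#' This keeps the chance-map thresholding consistent with the observed-map
#' rule and yields a usable (non-empty) cluster-size null even at reduced
#' bootstrap counts.
#'
#' @param null_maps Bootstrap null matrix (`draws x voxels`).
#' @param alpha Voxelwise level.
#' @return Logical matrix of the same shape: which voxels of each chance map
#'   survive.
#' @export
threshold_chance_maps <- function(null_maps, alpha = 0.001) {
  n <- nrow(null_maps)
  # rank from the top, per voxel: count of draws >= each draw (self included)
  cnt <- apply(null_maps, 2, function(v) {
    # #{k: v_k >= v_j} for each j
    length(v) - rank(v, ties.method = "min") + 1
  })
  # self-excluded count is cnt - 1
  (1 + (cnt - 1)) / (1 + n) < alpha
}

#' Pool a cluster-size null distribution from thresholded chance maps
#'
#' Collects the sizes of every connected cluster occurring in each
#' thresholded chance map into one pooled multiset.
#'
#' @param thresholded Logical matrix (`maps x voxels`) of surviving voxels
#'   per chance map, or a list of logical 3D arrays.
#' @param mask_flat Integer flat voxel indices mapping columns into the
#'   volume (required for the matrix form).
#' @param dim Volume shape (required for the matrix form).
#' @param connectivity 6 or 26.
#' @return A `cluster_size_null`: list with `sizes` (integer vector, possibly
#'   empty) and `n_maps`.
#' @export
cluster_size_null <- function(thresholded, mask_flat = NULL, dim = NULL,
                              connectivity = 26) {
  if (is.matrix(thresholded)) {
    stopifnot(!is.null(mask_flat), !is.null(dim))
    maps <- lapply(seq_len(nrow(thresholded)), function(i) {
      b <- array(FALSE, dim)
      b[mask_flat[thresholded[i, ]]] <- TRUE
      b
    })
    n_maps <- nrow(thresholded)
  } else {
    maps <- thresholded
    n_maps <- length(maps)
  }
  sizes <- integer(0)
  for (b in maps) {
    if (!any(b)) next
    sizes <- c(sizes, find_clusters(b, connectivity)$table$size)
  }
  structure(list(sizes = sizes, n_maps = n_maps),
            class = "cluster_size_null")
}

#' Cluster p-values and Benjamini-Hochberg significance
#'
#' Each observed cluster's p-value is the add-one tail probability of its
#' size in the pooled chance cluster-size distribution; the
#' Benjamini-Hochberg procedure is then applied across the observed clusters
#' at level `q`. If the chance distribution contains no clusters at all, the
#' minimum attainable p given the number of chance maps is assigned to every
#' cluster and a warning is raised.
#'
#' @param clusters Cluster tibble with a `size` column (from
#'   [find_clusters()]).
#' @param size_null A [cluster_size_null()].
#' @param q FDR level.
#' @return The cluster tibble with `p`, `p_fdr` and `significant` columns.
#' @export
cluster_pvalues_fdr <- function(clusters, size_null, q = 0.05) {
  m <- nrow(clusters)
  if (m == 0) {
    return(dplyr::mutate(clusters, p = numeric(0), p_fdr = numeric(0),
                         significant = logical(0)))
  }
  if (length(size_null$sizes) == 0) {
    warn(paste0("Empty cluster-size null distribution; assigning the ",
                "minimum attainable p = 1/(1 + ", size_null$n_maps,
                ") to all observed clusters."))
    p <- rep(1 / (1 + size_null$n_maps), m)
  } else {
    p <- vapply(clusters$size, function(s) {
      (1 + sum(size_null$sizes >= s)) / (1 + length(size_null$sizes))
    }, numeric(1))
  }
  p_fdr <- p.adjust(p, method = "BH")
  dplyr::mutate(clusters, p = p, p_fdr = p_fdr, significant = p_fdr <= q)
}

#' Group-level ROI decoding test
#'
#' Group accuracy is the mean of the per-subject true accuracies; its
#' p-value comes from the permutation/bootstrap null: one chance accuracy is
#' drawn per subject (with replacement) and averaged, `n_boot` times, and
#' the add-one tail probability of the observed group mean is reported.
#'
#' @param accuracies Numeric vector, one true accuracy per subject.
#' @param chance List (one element per subject) of chance-accuracy vectors
#'   from label-permuted re-analyses.
#' @param n_boot Bootstrap draws.
#' @param seed Integer seed.
#' @return Tibble with `group_accuracy`, `p`, `n_subjects`, `n_boot`.
#' @export
roi_group_test <- function(accuracies, chance, n_boot = 1e5, seed = 1L) {
  if (length(accuracies) != length(chance)) {
    abort("`accuracies` and `chance` must cover the same subjects.")
  }
  null <- bootstrap_group_null(chance, n_boot, seed)
  grp <- mean(accuracies)
  tibble::tibble(
    group_accuracy = grp,
    p = empirical_pvalue(grp, null),
    n_subjects = length(accuracies),
    n_boot = n_boot
  )
}
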