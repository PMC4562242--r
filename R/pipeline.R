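#' Configuration for a simulated decoding study
#'
#' Collects every parameter of the simulate -> betas -> decode -> inference
#' chain in one list. Defaults reproduce the emulated study design: ten runs
#' of 36 trials (6 conditions x 6 trials, 2 s each, 4-10 s jitter, TR 1 s),
#' 19 subjects, 4-way preference decoding with top-123-voxel feature
#' selection in the ROI, a radius-3 searchlight, 100 within-run label
#' permutations, 10^5 bootstrap draws, voxelwise p < 0.001 and cluster FDR
#' q < 0.05.
#'
#' @param n_subjects Number of simulated subjects.
#' @param design A [design_spec()].
#' @param volume_shape Simulated volume shape (voxels).
#' @param region_center,region_radius Active-region sphere (voxel units).
#' @param pattern_scale Effect size of the condition-specific patterns.
#' @param noise A [noise_spec()].
#' @param p_correct,p_respond Behavioral response probabilities.
#' @param roi_k Feature-selection sizes for the ROI analysis (may include
#'   `NA` for "no selection").
#' @param searchlight_radius Sphere radius in voxel units.
#' @param n_perm Within-run label permutations per subject.
#' @param n_boot Bootstrap draws for the group null.
#' @param alpha Voxelwise threshold.
#' @param q Cluster FDR level.
#' @param connectivity Cluster connectivity (6 or 26).
#' @param seed Global seed; all stage seeds derive from it.
#' @return A `study_config` list.
#' @export
study_config <- function(n_subjects = 19,
                         design = design_spec(),
                         volume_shape = c(12, 12, 12),
                         region_center = c(6, 6, 6),
                         region_radius = 4,
                         pattern_scale = 1,
                         noise = noise_spec(),
                         p_correct = 0.94,
                         p_respond = 0.98,
                         roi_k = 123,
                         searchlight_radius = 3,
                         n_perm = 100,
                         n_boot = 1e5,
                         alpha = 0.001,
                         q = 0.05,
                         connectivity = 26,
                         seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, q > 0, q < 1, n_subjects >= 1)
  structure(list(n_subjects = as.integer(n_subjects), design = design,
                 volume_shape = as.integer(volume_shape),
                 region_center = region_center,
                 region_radius = region_radius,
                 pattern_scale = pattern_scale, noise = noise,
                 p_correct = p_correct, p_respond = p_respond,
                 roi_k = roi_k, searchlight_radius = searchlight_radius,
                 n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
                 alpha = alpha, q = q, connectivity = connectivity,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Read a study configuration from a YAML document
#'
#' Scalar fields of the YAML override [study_config()] defaults; nested
#' `design:` and `noise:` blocks override [design_spec()] / [noise_spec()]
#' arguments.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  design <- do.call(design_spec, y$design %||% list())
  noise <- do.call(noise_spec, y$noise %||% list())
  y$design <- NULL
  y$noise <- NULL
  do.call(study_config, c(y, list(design = design, noise = noise)))
}

#' Simulate every subject of a study
#'
#' @param config A [study_config()].
#' @return List with `subjects` (list of [simulate_subject()] outputs),
#'   `patterns` (shared ground-truth [pattern_spec()]), `region_mask` (the
#'   active region, also the default ROI) and `brain_mask` (all voxels).
#' @export
simulate_study <- function(config) {
  patterns <- default_study_patterns(
    volume_shape = config$volume_shape, center = config$region_center,
    radius = config$region_radius, pattern_scale = config$pattern_scale,
    seed = config$seed)
  subjects <- purrr::map(seq_len(config$n_subjects), function(s) {
    simulate_subject(config$design, patterns, config$noise, subject = s,
                     p_correct = config$p_correct,
                     p_respond = config$p_respond, seed = config$seed)
  })
  list(subjects = subjects, patterns = patterns,
       region_mask = patterns$regions$active,
       brain_mask = array(TRUE, dim = config$volume_shape))
}

#' Estimate beta series for every subject of a study
#'
#' @param study Output of [simulate_study()].
#' @param mask Logical 3D mask (default: all voxels).
#' @return List of [beta_series()], one per subject.
#' @export
study_betas <- function(study, mask = NULL) {
  purrr::map(study$subjects, subject_beta_series, mask = mask)
}

# Restrict a beta series to the voxels of a mask.
mask_beta_series <- function(bs, mask) {
  stopifnot(!is.null(bs$voxels), !is.null(bs$dim))
  flat <- bs$voxels[, 1] + (bs$voxels[, 2] - 1L) * bs$dim[1] +
    (bs$voxels[, 3] - 1L) * bs$dim[1] * bs$dim[2]
  keep <- as.vector(mask)[flat]
  beta_series(bs$data[, keep, drop = FALSE], bs$labels,
              voxels = bs$voxels[keep, , drop = FALSE], dim = bs$dim)
}

# Beta series with condition labels permuted within runs among the trials
# eligible for `targets`.
permuted_beta_series <- function(bs, targets, seed) {
  map <- target_class_map(targets)
  eligible <- bs$labels$correct & bs$labels$condition %in% names(map)
  cond <- bs$labels$condition
  cond[eligible] <- permute_labels_within_runs(
    cond[eligible], bs$labels$run[eligible], seed = seed)
  bs$labels$condition <- cond
  bs
}

#' Group-level ROI decoding with permutation/bootstrap inference
#'
#' For each feature-selection size and each subject, runs the leave-one-run-
#' out GNB analysis on the ROI voxels plus `n_perm` label-permuted repeats,
#' then tests the group mean accuracy against the bootstrap null.
#'
#' @param betas_list List of per-subject [beta_series()].
#' @param roi_mask Logical 3D array selecting the ROI voxels.
#' @param targets Conditions or condition-to-class mapping.
#' @param k_features Vector of feature counts; use `NA` for no selection.
#' @param n_perm Label permutations per subject.
#' @param n_boot Bootstrap draws for the group null.
#' @param seed Integer seed.
#' @return Tibble with one row per feature count: `k`, `group_accuracy`,
#'   `p`, `chance`, plus list-columns `subject_accuracy` and `cv` (the
#'   per-subject `cv_result`s).
#' @export
decode_roi_group <- function(betas_list, roi_mask, targets, k_features = 123,
                             n_perm = 100, n_boot = 1e5, seed = 1L) {
  roi <- purrr::map(betas_list, mask_beta_series, mask = roi_mask)
  n_classes <- length(unique(unname(target_class_map(targets))))
  rows <- purrr::map(k_features, function(k) {
    kk <- if (is.na(k)) NULL else k
    kid <- if (is.na(k)) 0 else k
    cvs <- purrr::imap(roi, function(bs, s) {
      crossvalidate_loro(bs, targets, k_features = kk,
                         seed = derive_seed(seed, "roi", s, kid))
    })
    accs <- purrr::map_dbl(cvs, "accuracy")
    if (n_perm == 0) {
      return(tibble::tibble(k = k, group_accuracy = mean(accs), p = NA_real_,
                            chance = 1 / n_classes,
                            subject_accuracy = list(accs), cv = list(cvs)))
    }
    chance <- purrr::imap(roi, function(bs, s) {
      vapply(seq_len(n_perm), function(p) {
        pb <- permuted_beta_series(bs, targets,
                                   seed = derive_seed(seed, "roiperm", s, p))
        crossvalidate_loro(pb, targets, k_features = kk,
                           seed = derive_seed(seed, "roi", s, kid))$accuracy
      }, numeric(1))
    })
    test <- roi_group_test(accs, chance, n_boot = n_boot,
                           seed = derive_seed(seed, "roiboot", kid))
    tibble::tibble(k = k, group_accuracy = test$group_accuracy, p = test$p,
                   chance = 1 / n_classes,
                   subject_accuracy = list(accs), cv = list(cvs))
  })
  dplyr::bind_rows(rows)
}

#' Group-level searchlight analysis with cluster-corrected inference
#'
#' Runs the searchlight (true labels + `n_perm` within-run permutations) for
#' every subject, averages the per-subject accuracy maps into a group map,
#' builds the voxelwise bootstrap null, thresholds at `alpha`, extracts
#' connected clusters, assigns each a cluster-size p-value from the pooled
#' chance-map cluster distribution, applies Benjamini-Hochberg FDR at `q`,
#' and reports each cluster's peak-accuracy coordinate and group-level
#' scaled confusion matrix (subject cluster-average matrices, averaged
#' across subjects) with its diagonal-dominance flag.
#'
#' @param betas_list List of per-subject [beta_series()] on one grid.
#' @param mask Logical 3D brain mask.
#' @param targets Conditions or condition-to-class mapping.
#' @param radius Searchlight radius (voxel units).
#' @param n_perm Label permutations per subject.
#' @param n_boot Bootstrap draws for the group null maps.
#' @param alpha Voxelwise threshold.
#' @param q Cluster FDR level.
#' @param connectivity 6 or 26.
#' @param seed Integer seed.
#' @return A `group_searchlight` object: list with `group_map` and `p_map`
#'   (3D arrays), `clusters` (tibble: cluster, size, peak coordinates, p,
#'   p_fdr, significant, diagonal_dominant, confusion list-column),
#'   `size_null`, `subject_maps`, `sl` (per-subject `searchlight_result`s)
#'   and the parameters used.
#' @export
searchlight_group <- function(betas_list, mask, targets, radius = 3,
                              n_perm = 100, n_boot = 1e5, alpha = 0.001,
                              q = 0.05, connectivity = 26, seed = 1L) {
  sls <- purrr::imap(betas_list, function(bs, s) {
    run_searchlight(bs, mask = mask, radius = radius, targets = targets,
                    n_perm = n_perm, seed = derive_seed(seed, "sl", s))
  })
  dims <- sls[[1]]$dim
  flat <- sls[[1]]$center_flat
  for (sl in sls) {
    if (!identical(sl$center_flat, flat)) {
      abort("Subjects' searchlight maps are not on a shared grid.")
    }
  }
  ok <- Reduce(`&`, lapply(sls, function(sl) !is.na(sl$accuracy[flat])))
  flat_ok <- flat[ok]
  obs <- do.call(rbind, lapply(sls, function(sl) sl$accuracy[flat_ok]))
  group <- colMeans(obs)
  chance <- lapply(sls, function(sl) sl$chance[, ok, drop = FALSE])
  null_maps <- bootstrap_group_null(chance, n_boot,
                                    seed = derive_seed(seed, "slboot"))
  p_vox <- empirical_pvalue(group, null_maps)
  supra <- threshold_map(group, null_maps, alpha)

  binary <- array(FALSE, dims)
  binary[flat_ok[supra]] <- TRUE
  cl <- find_clusters(binary, connectivity)
  size_null <- cluster_size_null(threshold_chance_maps(null_maps, alpha),
                                 mask_flat = flat_ok, dim = dims,
                                 connectivity = connectivity)
  clusters <- cluster_pvalues_fdr(cl$table, size_null, q)

  group_map <- array(NA_real_, dims)
  group_map[flat_ok] <- group
  p_map <- array(NA_real_, dims)
  p_map[flat_ok] <- p_vox

  if (nrow(clusters) > 0) {
    extra <- purrr::map(clusters$cluster, function(id) {
      vox <- which(cl$labels == id)
      peak <- vox[which.max(group_map[vox])]
      pc <- arrayInd(peak, dims)[1, ]
      cms <- purrr::map(sls, ~ cluster_confusion(vox, .x))
      cm <- Reduce(`+`, cms) / length(cms)
      tibble::tibble(peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
                     peak_accuracy = group_map[peak],
                     diagonal_dominant = diagonal_dominant(cm),
                     confusion = list(cm), voxels = list(vox))
    })
    clusters <- dplyr::bind_cols(clusters, dplyr::bind_rows(extra))
  }

  structure(list(group_map = group_map, p_map = p_map, clusters = clusters,
                 size_null = size_null, subject_maps = obs, sl = sls,
                 mask_flat = flat_ok, classes = sls[[1]]$classes, dim = dims,
                 params = list(radius = radius, n_perm = n_perm,
                               n_boot = n_boot, alpha = alpha, q = q,
                               connectivity = connectivity, seed = seed)),
            class = "group_searchlight")
}

#' @export
print.group_searchlight <- function(x, ...) {
  ns <- sum(x$clusters$significant %||% logical(0))
  cat("<group_searchlight> ", nrow(x$subject_maps), " subjects, ",
      length(x$mask_flat), " centers, ", nrow(x$clusters),
      " supra-threshold cluster(s), ", ns, " FDR-significant\n", sep = "")
  invisible(x)
}

#' @export
tidy.group_searchlight <- function(x, ...) {
  dplyr::select(x$clusters, -dplyr::any_of(c("confusion", "voxels")))
}

#' @export
glance.group_searchlight <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$subject_maps),
    n_centers = length(x$mask_flat),
    mean_accuracy = mean(x$group_map[x$mask_flat]),
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant %||% logical(0))
  )
}

#' Run the complete study pipeline
#'
#' simulate -> per-subject beta series -> ROI decoding (4-way preference,
#' 2-way no-preference control, 2-way expected-outcome) -> searchlight
#' 4-way + control group inference.
#'
#' @param config A [study_config()].
#' @param searchlight Run the searchlight stages (the slow part)?
#' @return List with `config`, `study`, `betas`, `roi` (tibble across
#'   analyses and feature counts), `searchlight_4way`, `searchlight_control`.
#' @export
run_study <- function(config = study_config(), searchlight = TRUE) {
  study <- simulate_study(config)
  betas <- study_betas(study)
  analyses <- list(
    preference_4way = c("H1", "S1", "H2", "S2"),
    nopreference_2way = c("H3", "S3"),
    outcome_2way = c(H1 = "vegetable", S2 = "vegetable",
                     S1 = "meat", H2 = "meat")
  )
  roi <- purrr::imap(analyses, function(tg, nm) {
    ks <- if (nm == "preference_4way") config$roi_k else config$roi_k[1]
    dplyr::mutate(
      decode_roi_group(betas, study$region_mask, tg, k_features = ks,
                       n_perm = config$n_perm, n_boot = config$n_boot,
                       seed = derive_seed(config$seed, "roi", nm)),
      analysis = nm, .before = 1)
  })
  roi <- dplyr::bind_rows(roi)
  sl4 <- slc <- NULL
  if (searchlight) {
    sl4 <- searchlight_group(
      betas, study$brain_mask, analyses$preference_4way,
      radius = config$searchlight_radius, n_perm = config$n_perm,
      n_boot = config$n_boot, alpha = config$alpha, q = config$q,
      connectivity = config$connectivity,
      seed = derive_seed(config$seed, "sl4"))
    slc <- searchlight_group(
      betas, study$brain_mask, analyses$nopreference_2way,
      radius = config$searchlight_radius, n_perm = config$n_perm,
      n_boot = config$n_boot, alpha = config$alpha, q = config$q,
      connectivity = config$connectivity,
      seed = derive_seed(config$seed, "slc"))
  }
  structure(list(config = config, study = study, betas = betas, roi = roi,
                 searchlight_4way = sl4, searchlight_control = slc),
            class = "study_result")
}

#' Human-readable study report
#'
#' Prints group accuracies with p-values for every ROI analysis, the cluster
#' table (peak coordinates, sizes, p, FDR flags) and each significant
#' cluster's scaled confusion matrix.
#'
#' @param result A [run_study()] result.
#' @return `result`, invisibly.
#' @export
study_report <- function(result) {
  cat("== ROI decoding ==\n")
  roi <- dplyr::select(result$roi, "analysis", "k", "group_accuracy",
                       "chance", "p")
  print(as.data.frame(roi), row.names = FALSE, digits = 4)
  for (nm in c("searchlight_4way", "searchlight_control")) {
    x <- result[[nm]]
    if (is.null(x)) next
    cat("\n== ", nm, " ==\n", sep = "")
    if (nrow(x$clusters) == 0) {
      cat("No supra-threshold clusters; none significant.\n")
      next
    }
    print(as.data.frame(tidy(x)), row.names = FALSE, digits = 4)
    sig <- dplyr::filter(x$clusters, .data$significant)
    for (i in seq_len(nrow(sig))) {
      cat("\nCluster ", sig$cluster[i],
          " scaled confusion (% of row; rows sum to ~100):\n", sep = "")
      print(round(sig$confusion[[i]], 1))
    }
  }
  invisible(result)
}
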