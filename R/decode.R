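#' Z-score each sample across its voxels
#'
#' Removes mean and scale differences between samples: every row is centered
#' and divided by its population (divide-by-n) standard deviation across
#' voxels. Operating row-wise, this is idempotent and leaves classifier
#' rankings unchanged by any constant per-sample offset or gain.
#'
#' @param x Numeric matrix (samples x voxels) or a [beta_series()].
#' @return Same type as the input, rows standardized.
#' @export
znorm_samples <- function(x) {
  if (inherits(x, "beta_series")) {
    x$data <- znorm_samples(x$data)
    return(x)
  }
  stopifnot(is.matrix(x))
  if (ncol(x) < 2) abort("Per-sample z-scoring needs >= 2 voxels.")
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowMeans(xc^2))
  if (any(s == 0)) {
    abort("Zero-variance sample: cannot z-score a constant row.",
          class = "decodelight_degenerate_sample")
  }
  xc / s
}

#' One-way ANOVA F statistic per voxel
#'
#' The between/within mean-square ratio of each column of `x` grouped by
#' `labels` — the feature-selection score: voxels whose trial-wise estimates
#' vary most between conditions score highest.
#'
#' @param x Numeric matrix, samples x voxels.
#' @param labels Class label per sample (>= 2 classes, >= 2 samples each).
#' @return Numeric vector of F statistics, one per voxel.
#' @export
anova_f_scores <- function(x, labels) {
  labels <- as.factor(labels)
  k <- nlevels(labels)
  n <- nrow(x)
  if (k < 2) abort("ANOVA feature scoring needs >= 2 classes.")
  counts <- tabulate(labels, k)
  if (any(counts < 2)) {
    abort("Every class needs >= 2 samples for the one-way ANOVA.")
  }
  grand <- colMeans(x)
  group_sum <- rowsum(x, labels)            # k x V
  group_mean <- group_sum / counts
  ss_between <- colSums(counts * (group_mean -
                                    matrix(grand, k, ncol(x), byrow = TRUE))^2)
  ss_total <- colSums((x - matrix(grand, n, ncol(x), byrow = TRUE))^2)
  ss_within <- ss_total - ss_between
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

#' Indices of the k largest scores
#'
#' Ties are broken by ascending index, so the selection is deterministic.
#'
#' @param scores Numeric vector.
#' @param k Number of features to keep (<= length(scores)).
#' @return Integer vector of `k` indices, in descending score order.
#' @export
select_top_k <- function(scores, k) {
  if (k > length(scores)) {
    abort("`k` exceeds the number of features.",
          class = "decodelight_invalid_k")
  }
  order(-scores, seq_along(scores))[seq_len(k)]
}

#' Downsample classes to a common trial count
#'
#' Keeps, for each class, a seeded without-replacement draw of
#' `min(class counts)` samples, equalizing class counts in a training
#' partition. When the classes are already balanced all samples are kept and
#' no randomness is consumed.
#'
#' @param labels Class label per sample; every class must be non-empty.
#' @param seed Integer seed.
#' @return Sorted integer vector of kept sample indices.
#' @export
balance_training_set <- function(labels, seed = 1L) {
  labels <- as.factor(labels)
  if (any(tabulate(labels, nlevels(labels)) == 0)) {
    abort("Empty class: cannot balance.", class = "decodelight_empty_class")
  }
  idx_by_class <- split(seq_along(labels), labels)
  m <- min(lengths(idx_by_class))
  if (all(lengths(idx_by_class) == m)) return(seq_along(labels))
  kept <- with_seed(derive_seed(seed, "balance"), {
    lapply(idx_by_class, function(ix) {
      if (length(ix) == m) ix else sort(sample(ix, m))
    })
  })
  sort(unlist(kept, use.names = FALSE))
}

#' Gaussian naive Bayes: fit and predict
#'
#' `gnb_fit` estimates, per class, a per-feature mean and (population)
#' variance plus a class log-prior. Variances are floored at
#' `floor_factor x` the mean of all class-feature variances to keep
#' log-densities finite on (near-)constant features. Priors are uniform:
#' training partitions are balanced by construction. `gnb_predict` returns,
#' for each test sample, the class maximizing the sum of the class log-prior
#' and the per-feature Gaussian log-densities; ties go to the first class in
#' the model's canonical label order.
#'
#' @param x Training matrix (samples x features), >= 2 samples per class.
#' @param labels Class label per training sample.
#' @param floor_factor Relative variance floor.
#' @return `gnb_fit`: a `gnb_model`; `gnb_predict`: a factor of predicted
#'   labels with the model's class levels.
#' @export
gnb_fit <- function(x, labels, floor_factor = 1e-9) {
  labels <- as.factor(labels)
  k <- nlevels(labels)
  counts <- tabulate(labels, k)
  if (any(counts < 2)) abort("Each class needs >= 2 training samples.")
  mu <- rowsum(x, labels) / counts
  ex2 <- rowsum(x^2, labels) / counts
  v <- ex2 - mu^2
  fl <- floor_factor * mean(v)
  if (!is.finite(fl) || fl <= 0) fl <- 1e-12
  v[v < fl] <- fl
  structure(list(classes = levels(labels), means = mu, vars = v,
                 log_prior = rep(-log(k), k)),
            class = "gnb_model")
}

#' @rdname gnb_fit
#' @param model A fitted `gnb_model`.
#' @param newdata Test matrix (samples x features).
#' @export
gnb_predict <- function(model, newdata) {
  if (ncol(newdata) != ncol(model$means)) {
    abort("Feature count of `newdata` does not match the model.")
  }
  ll <- gnb_log_posterior(model, newdata)
  pred <- max.col(ll, ties.method = "first")
  factor(model$classes[pred], levels = model$classes)
}

# samples x classes matrix of unnormalized log-posteriors
gnb_log_posterior <- function(model, newdata) {
  k <- length(model$classes)
  n <- nrow(newdata)
  ll <- matrix(0, n, k)
  for (j in seq_len(k)) {
    mu <- model$means[j, ]
    v <- model$vars[j, ]
    d <- newdata - matrix(mu, n, length(mu), byrow = TRUE)
    ll[, j] <- model$log_prior[j] -
      0.5 * sum(log(2 * pi * v)) -
      0.5 * colSums(t(d^2) / v)
  }
  ll
}

#' Leave-one-run-out cross-validated decoding
#'
#' For each fold one run is held out. The training partition is filtered to
#' eligible trials, balanced across classes with a per-fold seeded draw,
#' z-scored per sample, optionally reduced to the top-`k_features` voxels by
#' one-way-ANOVA score (computed on the training partition only), and a
#' Gaussian naive Bayes model is fit and applied to the held-out run's
#' eligible trials. Confusion counts are pooled over folds and the overall
#' accuracy is pooled correct predictions over pooled predictions.
#'
#' By default a trial is eligible when its `correct` label is true; for
#' no-preference control conditions the behavioral simulator defines
#' `correct = responded`, so the same rule keeps every responded control
#' trial. Pass `eligible` to override.
#'
#' @param betas A [beta_series()].
#' @param targets Either a character vector of conditions (each its own
#'   class) or a named character vector mapping conditions to merged class
#'   labels (e.g. `c(H1 = "veg", S2 = "veg", S1 = "meat", H2 = "meat")` for
#'   expected-outcome decoding).
#' @param k_features Number of voxels kept by feature selection, or `NULL`
#'   to use all voxels.
#' @param seed Integer seed (per-fold balancing draws derive from it).
#' @param eligible Optional logical vector overriding the correct-trial
#'   filter (length = samples).
#' @return A `cv_result`: list with `accuracy`, `folds` (tibble of per-fold
#'   accuracies), `confusion` (count matrix), `confusion_pct` (row-scaled),
#'   `selected` (per-fold feature indices), `classes`, `n_samples`.
#' @export
crossvalidate_loro <- function(betas, targets, k_features = NULL, seed = 1L,
                               eligible = NULL) {
  labels <- betas$labels
  map <- target_class_map(targets)
  if (is.null(eligible)) eligible <- labels$correct
  keep <- eligible & labels$condition %in% names(map)
  cls <- factor(unname(map[labels$condition[keep]]), levels = unique(unname(map)))
  x <- betas$data[keep, , drop = FALSE]
  run <- labels$run[keep]
  runs <- sort(unique(labels$run))
  if (length(runs) < 2) abort("Leave-one-run-out needs >= 2 runs.")
  if (!is.null(k_features) && k_features > ncol(x)) {
    abort("`k_features` exceeds the number of voxels.",
          class = "decodelight_invalid_k")
  }

  k <- nlevels(cls)
  conf <- matrix(0L, k, k, dimnames = list(actual = levels(cls),
                                           predicted = levels(cls)))
  fold_rows <- list()
  selected <- list()
  for (fi in seq_along(runs)) {
    r <- runs[fi]
    tr_idx <- which(run != r)
    te_idx <- which(run == r)
    if (length(te_idx) == 0) next
    tr_cls <- droplevels(cls[tr_idx])
    if (nlevels(tr_cls) < k) {
      abort(paste0("Training fold (held-out run ", r,
                   ") lacks at least one target class."))
    }
    bal <- balance_training_set(cls[tr_idx], seed = derive_seed(seed, "fold", fi))
    tr_idx <- tr_idx[bal]
    xtr <- znorm_samples(x[tr_idx, , drop = FALSE])
    xte <- znorm_samples(x[te_idx, , drop = FALSE])
    feat <- seq_len(ncol(x))
    if (!is.null(k_features)) {
      f <- anova_f_scores(xtr, cls[tr_idx])
      feat <- select_top_k(f, k_features)
      xtr <- xtr[, feat, drop = FALSE]
      xte <- xte[, feat, drop = FALSE]
    }
    model <- gnb_fit(xtr, cls[tr_idx])
    pred <- gnb_predict(model, xte)
    actual <- cls[te_idx]
    conf_f <- table(actual = actual, predicted = pred)
    conf <- conf + as.matrix(conf_f)
    fold_rows[[fi]] <- tibble::tibble(
      run = r, n_test = length(te_idx),
      accuracy = mean(pred == actual)
    )
    selected[[fi]] <- feat
  }
  total <- sum(conf)
  structure(list(
    accuracy = sum(diag(conf)) / total,
    folds = dplyr::bind_rows(fold_rows),
    confusion = conf,
    confusion_pct = scale_confusion(conf),
    selected = selected,
    classes = levels(cls),
    n_samples = total
  ), class = "cv_result")
}

# Normalize the two accepted `targets` forms into a named condition -> class map.
target_class_map <- function(targets) {
  if (is.null(names(targets))) {
    stats::setNames(as.character(targets), as.character(targets))
  } else {
    stats::setNames(as.character(targets), names(targets))
  }
}

#' Row-scale a confusion matrix to percentages
#'
#' Divides each row (actual class) by its sum and multiplies by 100, so each
#' cell is the percentage of that class's trials assigned to each predicted
#' class and every row sums to 100.
#'
#' @param cm Square count matrix with positive row sums.
#' @return Numeric matrix of percentages.
#' @export
scale_confusion <- function(cm) {
  rs <- rowSums(cm)
  if (any(rs == 0)) {
    abort("Confusion matrix has an empty row; cannot scale.",
          class = "decodelight_zero_row")
  }
  sweep(cm, 1, rs, "/") * 100
}

#' Is a scaled confusion matrix diagonal-dominant?
#'
#' TRUE iff in every row the diagonal entry strictly exceeds every
#' off-diagonal entry — i.e. each class is most often assigned to itself.
#'
#' @param cm Square (scaled) confusion matrix.
#' @return Logical scalar.
#' @export
diagonal_dominant <- function(cm) {
  stopifnot(nrow(cm) == ncol(cm))
  for (i in seq_len(nrow(cm))) {
    if (any(cm[i, -i] >= cm[i, i])) return(FALSE)
  }
  TRUE
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", length(x$classes), "-way GNB, ",
      nrow(x$folds), " folds, accuracy ",
      sprintf("%.3f", x$accuracy), " (n = ", x$n_samples, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) {
  cm <- x$confusion
  pct <- x$confusion_pct
  tibble::tibble(
    actual = rep(rownames(cm), times = ncol(cm)),
    predicted = rep(colnames(cm), each = nrow(cm)),
    n = as.vector(cm),
    percent = as.vector(pct)
  )
}

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    n_classes = length(x$classes),
    n_folds = nrow(x$folds),
    n_predictions = x$n_samples,
    chance = 1 / length(x$classes),
    diagonal_dominant = diagonal_dominant(x$confusion_pct)
  )
}

#' @export
autoplot.cv_result <- function(object, ...) {
  d <- tidy(object)
  d$actual <- factor(d$actual, levels = rev(object$classes))
  d$predicted <- factor(d$predicted, levels = object$classes)
  ggplot2::ggplot(d, ggplot2::aes(.data$predicted, .data$actual,
                                  fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$percent)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "grey92", high = "firebrick") +
    ggplot2::labs(x = "Predicted", y = "Actual", fill = "% of row",
                  title = sprintf("GNB leave-one-run-out accuracy %.1f%%",
                                  100 * object$accuracy)) +
    ggplot2::theme_minimal()
}
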