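test_that("per-sample z-scoring standardizes rows with the population SD", {
  x <- matrix(c(1, 2, 3,
                4, 4, 10), 2, 3, byrow = TRUE)
  z <- znorm_samples(x)
  expect_equal(rowMeans(z), c(0, 0), tolerance = 1e-10)
  expect_equal(sqrt(rowMeans(z^2)), c(1, 1), tolerance = 1e-10)
  # hand arithmetic for (1, 2, 3): population SD = sqrt(2/3)
  expect_equal(z[1, ], c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-10)
  # idempotence
  expect_equal(znorm_samples(z), z, tolerance = 1e-10)
})

test_that("z-scoring rejects degenerate inputs", {
  expect_error(znorm_samples(matrix(1, 2, 1)), ">= 2 voxels")
  expect_error(znorm_samples(matrix(c(5, 5, 5, 1, 2, 3), 2, 3, byrow = TRUE)),
               class = "decodelight_degenerate_sample")
})

test_that("ANOVA F scores vanish for equal class means", {
  x <- matrix(c(1, 2, 1, 2, 1, 2, 1, 2), 8, 3)
  labels <- rep(c("a", "b"), each = 4)
  f <- anova_f_scores(x, labels)
  expect_true(all(abs(f) < 1e-12))
})

test_that("two-class F equals the squared pooled t statistic", {
  set.seed(5)
  x <- matrix(rnorm(20 * 6), 20, 6)
  labels <- rep(c("a", "b"), each = 10)
  f <- anova_f_scores(x, labels)
  t2 <- apply(x, 2, function(v) {
    t.test(v[1:10], v[11:20], var.equal = TRUE)$statistic^2
  })
  expect_equal(f, unname(t2), tolerance = 1e-10)
})

test_that("F scores match a brute-force sums-of-squares decomposition", {
  set.seed(6)
  x <- matrix(rnorm(24 * 10), 24, 10)
  labels <- rep(c("w", "x", "y", "z"), 6)
  f <- anova_f_scores(x, labels)
  oracle <- apply(x, 2, function(v) {
    gm <- mean(v)
    ssb <- 0; ssw <- 0
    for (g in unique(labels)) {
      vg <- v[labels == g]
      ssb <- ssb + length(vg) * (mean(vg) - gm)^2
      ssw <- ssw + sum((vg - mean(vg))^2)
    }
    (ssb / 3) / (ssw / 20)
  })
  expect_equal(f, unname(oracle), tolerance = 1e-10)
  # and the stats::oneway.test cross-check
  ref <- apply(x, 2, function(v) {
    unname(oneway.test(v ~ factor(labels), var.equal = TRUE)$statistic)
  })
  expect_equal(f, unname(ref), tolerance = 1e-8)
})

test_that("ANOVA scoring validates its preconditions", {
  x <- matrix(rnorm(6), 3, 2)
  expect_error(anova_f_scores(x, c("a", "a", "a")), ">= 2 classes")
  expect_error(anova_f_scores(x, c("a", "a", "b")), ">= 2 samples")
})

test_that("top-k selection orders by score with index tie-breaks", {
  expect_equal(sort(select_top_k(c(0.1, 5, 3), 2)), c(2, 3))
  expect_equal(sort(select_top_k(c(0.1, 5, 3), 3)), 1:3)
  expect_error(select_top_k(c(1, 2), 3), class = "decodelight_invalid_k")
  # ties: lowest indices win, verified against a stable-sort oracle
  set.seed(7)
  for (i in 1:20) {
    s <- sample(c(1, 2, 2, 3, 3, 3, 5))
    k <- sample(7, 1)
    got <- select_top_k(s, k)
    ord <- sort.list(-s, method = "radix") # stable: ascending index on ties
    expect_equal(got, ord[seq_len(k)])
  }
})

test_that("balancing downsamples every class to the minimum count", {
  labels <- rep(c("a", "b", "c", "d"), c(10, 8, 9, 8))
  kept <- balance_training_set(labels, seed = 3)
  expect_equal(as.vector(table(labels[kept])), rep(8L, 4))
  # kept indices are a subset of each class's own indices
  for (g in c("a", "b", "c", "d")) {
    expect_true(all(kept[labels[kept] == g] %in% which(labels == g)))
  }
  # already balanced input keeps everything
  lab2 <- rep(c("a", "b"), each = 5)
  expect_equal(balance_training_set(lab2, seed = 1), 1:10)
  expect_error(balance_training_set(factor("a", levels = c("a", "b"))),
               class = "decodelight_empty_class")
})

test_that("the GNB decision boundary sits between symmetric classes", {
  x <- matrix(c(-1, -1.2, -0.8, 1, 1.2, 0.8), 6, 1)
  labels <- rep(c("lo", "hi"), each = 3)
  m <- gnb_fit(x, labels)
  expect_equal(as.character(gnb_predict(m, matrix(-0.2, 1, 1))), "lo")
  expect_equal(as.character(gnb_predict(m, matrix(0.2, 1, 1))), "hi")
})

test_that("GNB predictions equal a brute-force posterior evaluation", {
  set.seed(11)
  for (rep in 1:25) {
    n_feat <- sample(2:6, 1)
    train <- matrix(rnorm(40 * n_feat), 40, n_feat)
    labels <- factor(sample(rep(c("c1", "c2", "c3", "c4"), 10)))
    test <- matrix(rnorm(15 * n_feat), 15, n_feat)
    m <- gnb_fit(train, labels)
    got <- gnb_predict(m, test)
    # independent evaluation: per-class dnorm log-densities, summed in loops
    want <- apply(test, 1, function(s) {
      lp <- vapply(seq_along(m$classes), function(j) {
        sum(dnorm(s, m$means[j, ], sqrt(m$vars[j, ]), log = TRUE)) +
          m$log_prior[j]
      }, numeric(1))
      m$classes[which.max(lp)]
    })
    expect_identical(as.character(got), want)
  }
})

test_that("GNB agrees with an off-the-shelf naive Bayes on separated data", {
  skip_if_not_installed("e1071")
  set.seed(12)
  centers <- matrix(rnorm(4 * 5, sd = 6), 4, 5)
  labels <- factor(rep(c("a", "b", "c", "d"), each = 8))
  train <- centers[as.integer(labels), ] + matrix(rnorm(32 * 5), 32, 5)
  test <- centers[rep(1:4, 5), ] + matrix(rnorm(20 * 5), 20, 5)
  m <- gnb_fit(train, labels)
  ref <- e1071::naiveBayes(train, labels)
  expect_identical(as.character(gnb_predict(m, test)),
                   as.character(predict(ref, test)))
})

test_that("duplicating the training data leaves the GNB model unchanged", {
  set.seed(13)
  x <- matrix(rnorm(20 * 4), 20, 4)
  labels <- rep(c("a", "b"), 10)
  m1 <- gnb_fit(x, labels)
  m2 <- gnb_fit(rbind(x, x), c(labels, labels))
  expect_equal(m1$means, m2$means, tolerance = 1e-12)
  expect_equal(m1$vars, m2$vars, tolerance = 1e-12)
})

test_that("GNB validates feature dimensions", {
  m <- gnb_fit(matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5))
  expect_error(gnb_predict(m, matrix(0, 1, 3)), "Feature count")
})

test_that("separable synthetic classes are decoded perfectly", {
  bs <- make_class_betas(n_runs = 3, per_class = 4, sep = 10, noise_sd = 0.1,
                         seed = 21)
  cv <- crossvalidate_loro(bs, c("H1", "S1", "H2", "S2"), seed = 2)
  expect_equal(cv$accuracy, 1.0)
  expect_true(diagonal_dominant(cv$confusion_pct))
})

test_that("null data decode at chance within the binomial interval", {
  bs <- make_class_betas(n_runs = 5, per_class = 8, sep = 0, seed = 22)
  cv <- crossvalidate_loro(bs, c("H1", "S1", "H2", "S2"), seed = 3)
  n <- cv$n_samples
  half_width <- 1.96 * sqrt(0.25 * 0.75 / n)
  expect_lt(abs(cv$accuracy - 0.25), half_width + 0.02)
})

test_that("confusion counts pool to the total predictions across folds", {
  bs <- make_class_betas(n_runs = 4, per_class = 3, sep = 1, seed = 23)
  cv <- crossvalidate_loro(bs, c("H1", "S1", "H2", "S2"), seed = 4)
  expect_equal(sum(cv$confusion), sum(cv$folds$n_test))
  expect_equal(cv$accuracy, sum(diag(cv$confusion)) / sum(cv$confusion))
  # row sums equal per-class eligible counts
  counts <- table(bs$labels$condition)
  expect_equal(unname(rowSums(cv$confusion)),
               as.numeric(counts[cv$classes]))
})

test_that("feature selection uses the training partition only", {
  bs <- make_class_betas(n_runs = 3, per_class = 6, n_vox = 20, sep = 3,
                         seed = 24)
  # demean the class signal within each sample so the per-sample z-scoring
  # cannot leak class information into an otherwise uninformative voxel
  bs$data <- bs$data - rowMeans(bs$data)
  cv_base <- crossvalidate_loro(bs, c("H1", "S1", "H2", "S2"),
                                k_features = 5, seed = 5)
  # inject a voxel that is informative ONLY in run 0 (a test-only signal for
  # the fold that holds out run 0)
  set.seed(99)
  inj <- rnorm(nrow(bs$data), sd = 0.01)
  r0 <- bs$labels$run == 0
  inj[r0] <- match(bs$labels$condition[r0], c("H1", "S1", "H2", "S2")) * 50
  bs2 <- bs
  bs2$data <- cbind(bs$data, inj)
  cv_inj <- crossvalidate_loro(bs2, c("H1", "S1", "H2", "S2"),
                               k_features = 5, seed = 5)
  # fold 1 (held-out run 0) trains without run 0: its selection ignores the
  # injected voxel (prediction itself still sees it through the per-sample
  # z-scoring, which is applied before selection)
  expect_identical(cv_base$selected[[1]], cv_inj$selected[[1]])
  expect_false((ncol(bs$data) + 1) %in% cv_inj$selected[[1]])
})

test_that("correctness filtering excludes ineligible trials from decoding", {
  bs <- make_class_betas(n_runs = 3, per_class = 4, sep = 8, seed = 25)
  bs$labels$correct[seq(1, nrow(bs$data), by = 4)] <- FALSE
  cv <- crossvalidate_loro(bs, c("H1", "S1", "H2", "S2"), seed = 6)
  expect_equal(cv$n_samples, sum(bs$labels$correct))
})

test_that("merged-class targets pool their conditions' trials", {
  bs <- make_class_betas(n_runs = 3, per_class = 4, sep = 8, seed = 26)
  cv <- crossvalidate_loro(bs, c(H1 = "veg", S2 = "veg",
                                 S1 = "meat", H2 = "meat"), seed = 7)
  expect_equal(cv$classes, c("veg", "meat"))
  counts <- table(bs$labels$condition)
  expect_equal(unname(rowSums(cv$confusion)),
               c(counts[["H1"]] + counts[["S2"]],
                 counts[["S1"]] + counts[["H2"]]))
})

test_that("cross-validation enforces its preconditions", {
  bs <- make_class_betas(n_runs = 1, per_class = 4, seed = 27)
  expect_error(crossvalidate_loro(bs, c("H1", "S1")), ">= 2 runs")
  bs2 <- make_class_betas(n_runs = 3, per_class = 4, n_vox = 6, seed = 28)
  expect_error(crossvalidate_loro(bs2, c("H1", "S1"), k_features = 7),
               class = "decodelight_invalid_k")
})

test_that("confusion scaling yields rows that sum to 100", {
  cm <- matrix(c(3, 1, 0, 2,
                 0, 5, 1, 0,
                 1, 1, 4, 0,
                 2, 0, 0, 4), 4, 4, byrow = TRUE)
  s <- scale_confusion(cm)
  expect_equal(unname(rowSums(s)), rep(100, 4), tolerance = 1e-9)
  expect_equal(unname(scale_confusion(diag(6, 4))), diag(100, 4))
  expect_equal(unname(scale_confusion(matrix(1, 1, 4) %x% diag(1, 1))[1, ]),
               rep(25, 4))
  expect_error(scale_confusion(matrix(c(0, 0, 1, 2), 2, 2, byrow = TRUE)),
               class = "decodelight_zero_row")
})

test_that("diagonal dominance matches an exhaustive pairwise scan", {
  expect_true(diagonal_dominant(diag(100, 4)))
  bad <- diag(50, 4); bad[1, 2] <- 60
  expect_false(diagonal_dominant(bad))
  set.seed(31)
  for (i in 1:30) {
    m <- matrix(runif(16), 4, 4)
    brute <- all(vapply(1:4, function(r) {
      all(m[r, r] > m[r, setdiff(1:4, r)])
    }, logical(1)))
    expect_identical(diagonal_dominant(m), brute)
  }
})

test_that("cv_result tidiers expose accuracy and confusion in tidy form", {
  bs <- make_class_betas(n_runs = 3, per_class = 4, sep = 8, seed = 29)
  cv <- crossvalidate_loro(bs, c("H1", "S1", "H2", "S2"), seed = 8)
  td <- tidy(cv)
  expect_equal(nrow(td), 16)
  expect_equal(sum(td$n), cv$n_samples)
  gl <- glance(cv)
  expect_equal(gl$accuracy, cv$accuracy)
  expect_equal(gl$chance, 0.25)
  p <- autoplot(cv)
  expect_s3_class(p, "ggplot")
})
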