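test_that("within-run permutation preserves per-run label multisets", {
  labels <- c("a", "b", "c", "d", "a", "a", "b", "b")
  runs <- c(0, 0, 0, 0, 1, 1, 1, 1)
  for (s in 1:20) {
    p <- permute_labels_within_runs(labels, runs, seed = s)
    for (r in 0:1) {
      expect_equal(sort(p[runs == r]), sort(labels[runs == r]))
    }
  }
  # single-trial runs are unchanged
  expect_identical(permute_labels_within_runs("x", 0, seed = 1), "x")
})

test_that("permutations are uniform over arrangements", {
  labels <- c("a", "b", "c", "d")
  runs <- rep(0, 4)
  n <- 1000
  seen <- vapply(seq_len(n), function(s) {
    paste(permute_labels_within_runs(labels, runs, seed = s), collapse = "")
  }, character(1))
  counts <- table(seen)
  expect_equal(length(counts), 24) # all 4! arrangements occur
  expected <- n / 24
  bound <- 3 * sqrt(n * (1 / 24) * (23 / 24))
  expect_true(all(abs(counts - expected) <= bound))
})

test_that("degenerate chance sets give a degenerate bootstrap null", {
  null <- bootstrap_group_null(list(c(0.3, 0.3), c(0.3, 0.3)), 100, seed = 1)
  expect_equal(length(null), 100)
  expect_true(all(null == 0.3))
})

test_that("the bootstrap null enumerates subject combinations", {
  chance <- list(c(0.2, 0.4), c(0.1, 0.5))
  null <- bootstrap_group_null(chance, 8000, seed = 2)
  # hand enumeration: averages of one value per subject, all distinct
  want <- sort(c((0.2 + 0.1) / 2, (0.2 + 0.5) / 2,
                 (0.4 + 0.1) / 2, (0.4 + 0.5) / 2))
  expect_equal(sort(unique(round(null, 12))), want)
  # each combination is equally likely: counts within 3 binomial SDs
  counts <- table(round(null, 12))
  bound <- 3 * sqrt(8000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 2000) <= bound))
  # null mean close to the mean of subject means
  se <- sd(null) / sqrt(length(null))
  expect_lt(abs(mean(null) - 0.3), 3 * se + 1e-6)
})

test_that("the voxelwise bootstrap null averages maps across subjects", {
  chance <- list(matrix(c(1, 0, 0, 1), 2, 2), matrix(c(1, 0, 0, 1), 2, 2))
  null <- bootstrap_group_null(chance, 50, seed = 3)
  expect_equal(dim(null), c(50, 2))
  # with identical subjects every draw averages identical rows
  expect_true(all(null %in% c(0, 0.5, 1)))
})

test_that("empirical p-values follow the add-one rule", {
  null <- seq(0, 1, length.out = 1e5)
  expect_equal(empirical_pvalue(2, null), 1 / (1e5 + 1))
  expect_lt(abs(empirical_pvalue(stats::median(null), null) - 0.5),
            1.5 / length(null))
  # counting-loop oracle on random inputs
  set.seed(4)
  for (i in 1:20) {
    nd <- rnorm(57)
    obs <- rnorm(1)
    cnt <- 0
    for (v in nd) if (v >= obs) cnt <- cnt + 1
    expect_equal(empirical_pvalue(obs, nd), (1 + cnt) / 58)
  }
  # monotone non-increasing in the observed statistic
  obs <- sort(rnorm(20))
  p <- empirical_pvalue(obs, rnorm(200))
  expect_true(all(diff(p) <= 0))
})

test_that("map thresholding matches a brute-force voxel loop", {
  set.seed(5)
  null <- matrix(runif(200 * 30), 200, 30)
  obs <- runif(30)
  expect_true(all(threshold_map(obs, null, alpha = 1)))
  expect_false(any(threshold_map(obs, null, alpha = 1 / 500)))
  got <- threshold_map(obs, null, alpha = 0.05)
  want <- vapply(seq_len(30), function(v) {
    (1 + sum(null[, v] >= obs[v])) / 201 < 0.05
  }, logical(1))
  expect_identical(got, want)
  expect_error(threshold_map(obs[1:10], null), "different grids")
})

test_that("cluster finding matches an independent component labeling", {
  skip_if_not_installed("igraph")
  igraph_oracle <- function(binary, connectivity) {
    vox <- which(binary)
    if (length(vox) == 0) return(integer(0))
    coords <- arrayInd(vox, dim(binary))
    edges <- NULL
    if (length(vox) > 1) {
      for (i in seq_along(vox)) {
        for (j in seq_along(vox)) {
          if (i >= j) next
          d <- abs(coords[i, ] - coords[j, ])
          adj <- if (connectivity == 6) sum(d) == 1 else
            all(d <= 1) && sum(d) > 0
          if (adj) edges <- rbind(edges, c(i, j))
        }
      }
    }
    g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
    if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
    sort(as.integer(table(igraph::components(g)$membership)))
  }
  set.seed(6)
  for (conn in c(6, 26)) {
    for (i in 1:5) {
      b <- array(runif(6 * 5 * 4) < 0.3, c(6, 5, 4))
      got <- sort(find_clusters(b, conn)$table$size)
      expect_equal(got, igraph_oracle(b, conn))
    }
  }
})

test_that("simple cluster geometries are labeled correctly", {
  b <- array(FALSE, c(5, 5, 5))
  b[1, 1, 1] <- TRUE
  b[5, 5, 5] <- TRUE
  cl <- find_clusters(b, 26)
  expect_equal(sort(cl$table$size), c(1, 1))
  b2 <- array(FALSE, c(4, 4, 4))
  b2[2:3, 2:3, 2:3] <- TRUE
  for (conn in c(6, 26)) {
    expect_equal(find_clusters(b2, conn)$table$size, 8)
  }
  # diagonal voxels: connected under 26, separate under 6
  b3 <- array(FALSE, c(3, 3, 3))
  b3[1, 1, 1] <- TRUE
  b3[2, 2, 2] <- TRUE
  expect_equal(nrow(find_clusters(b3, 26)$table), 1)
  expect_equal(nrow(find_clusters(b3, 6)$table), 2)
})

test_that("cluster-size nulls pool sizes across chance maps", {
  m1 <- array(FALSE, c(4, 4, 4)); m1[1:2, 1, 1] <- TRUE # one size-2 cluster
  m2 <- array(FALSE, c(4, 4, 4)); m2[c(1, 16)] <- TRUE  # two singletons
  m3 <- array(FALSE, c(4, 4, 4))                        # empty
  null <- cluster_size_null(list(m1, m2, m3), connectivity = 26)
  expect_equal(sort(null$sizes), c(1, 1, 2))
  expect_equal(null$n_maps, 3)
  # invariant to map order
  null2 <- cluster_size_null(list(m3, m2, m1), connectivity = 26)
  expect_equal(sort(null2$sizes), sort(null$sizes))
})

test_that("chance-map self-thresholding retains only per-voxel extremes", {
  set.seed(7)
  null <- matrix(rnorm(1000 * 5), 1000, 5)
  thr <- threshold_chance_maps(null, alpha = 0.001)
  expect_equal(dim(thr), dim(null))
  # at alpha = 1/1000 exactly the strict per-voxel maximum survives
  for (v in 1:5) {
    expect_equal(which(thr[, v]), which.max(null[, v]))
  }
  # nothing survives a level below the attainable floor
  expect_false(any(threshold_chance_maps(null, alpha = 1 / 2000)))
})

test_that("BH cluster correction reproduces the hand-run procedure", {
  clusters <- tibble::tibble(cluster = 1:3, size = c(50, 20, 3))
  size_null <- structure(list(sizes = integer(0), n_maps = 100),
                         class = "cluster_size_null")
  # empty null: minimum attainable p with a warning
  expect_warning(out <- cluster_pvalues_fdr(clusters, size_null, q = 0.05),
                 "minimum attainable")
  expect_true(all(out$p == 1 / 101))
  # hand-constructed p-values through a fake null
  null2 <- structure(list(sizes = c(rep(1, 979), rep(2, 15), rep(5, 5), 60),
                          n_maps = 100), class = "cluster_size_null")
  out2 <- cluster_pvalues_fdr(clusters, null2, q = 0.05)
  # tail counts: sizes >= 50 and >= 20 catch only the single 60;
  # sizes >= 3 catch the five 5s plus the 60
  expect_equal(out2$p, c(2 / 1001, 2 / 1001, 7 / 1001))
  expect_true(all(out2$significant))
})

test_that("BH selection equals the brute-force largest-k definition", {
  bh_brute <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    k <- max(c(0, which(ps <= q * seq_len(m) / m)))
    sig <- logical(m)
    if (k > 0) sig[o[seq_len(k)]] <- TRUE
    sig
  }
  # the worked example: (0.001, 0.02, 0.3) at q = 0.05 -> two smallest pass
  p0 <- c(0.001, 0.02, 0.3)
  expect_equal(p.adjust(p0, "BH") <= 0.05, c(TRUE, TRUE, FALSE))
  expect_equal(bh_brute(p0, 0.05), c(TRUE, TRUE, FALSE))
  set.seed(8)
  for (i in 1:30) {
    p <- runif(sample(3:12, 1))^2
    q <- runif(1, 0.01, 0.2)
    expect_equal(p.adjust(p, "BH") <= q, bh_brute(p, q))
  }
  # boundary behaviors
  expect_true(all(p.adjust(rep(0.04, 5), "BH") <= 0.05))
  expect_false(any(p.adjust(c(0.2, 0.5, 0.9), "BH") <= 0.05))
})

test_that("the ROI group test combines accuracies and the bootstrap null", {
  # perfect decoding against chance-level permutations: minimum attainable p
  chance <- purrr::map(1:4, function(s) runif(10, 0.2, 0.3))
  out <- roi_group_test(c(1, 1, 1, 1), chance, n_boot = 500, seed = 9)
  expect_equal(out$p, 1 / 501)
  expect_equal(out$group_accuracy, 1)
  out2 <- roi_group_test(c(0.2, 0.3), list(runif(5), runif(5)),
                         n_boot = 100, seed = 10)
  expect_equal(out2$group_accuracy, 0.25)
  expect_error(roi_group_test(c(0.5, 0.5), list(runif(5))), "same subjects")
})
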