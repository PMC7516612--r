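# Mean-shift cluster recognition: normalization, kernels, clustering,
# per-cluster statistics, and invariants.

test_that("normalization maps each dimension to [0, 1]", {
  nc <- normalize_points(cbind(c(2, 4, 6)))
  expect_equal(unname(nc$points[, 1]), c(0, 0.5, 1))
  # already-[0,1] data with attained endpoints is unchanged
  x <- cbind(c(0, 0.3, 1), c(0, 1, 0.5))
  expect_equal(unname(normalize_points(x)$points), unname(x))
  # constant dimension -> all 0.5, flagged
  nc2 <- normalize_points(cbind(c(1, 2, 3), c(7, 7, 7)))
  expect_true(nc2$degenerate[2])
  expect_equal(unname(nc2$points[, 2]), rep(0.5, 3))
})

test_that("kernel weights follow the neighborhood rule", {
  expect_equal(kernel_weight(0.3, "flat", D = 0.5), 1)
  expect_equal(kernel_weight(0.5, "flat", D = 0.5), 0)       # outside NH
  expect_equal(kernel_weight(0, "gaussian"), 1)
  expect_equal(kernel_weight(0.2, "gaussian", D = 0.6, ell = 0.2), exp(-1))
  expect_equal(kernel_weight(0.7, "gaussian", D = 0.6, ell = 0.2), 0)
  expect_error(kernel_weight(-0.1), "nonnegative")
})

test_that("hand-computed 1-D case: two tight pairs give two clusters", {
  X <- cbind(c(0.0, 0.1, 0.9, 1.0))
  ms <- mean_shift(X, kernel = "flat", D = 0.15, merge_dist = 0.05)
  expect_equal(ms$n_clusters, 2)
  expect_equal(sort(ms$sizes), c(2, 2))
  expect_equal(sort(ms$modes[, 1]), c(0.05, 0.95), tolerance = 1e-6)
  # identical points collapse to one cluster immediately
  same <- mean_shift(cbind(rep(2, 5), rep(3, 5)))
  expect_equal(same$n_clusters, 1)
})

test_that("cluster counts respect their structural bounds", {
  set.seed(11)
  X <- matrix(runif(60), 30, 2)
  # D below the minimum inter-point distance: every point is a singleton
  dmin <- min(dist(normalize_points(X)$points))
  all_single <- mean_shift(X, kernel = "flat", D = dmin * 0.99,
                           merge_dist = dmin * 0.5)
  expect_equal(all_single$n_clusters, 30)
  # flat kernel with D >= sqrt(J) sees every point: one cluster
  one <- mean_shift(X, kernel = "flat", D = sqrt(2) + 0.01)
  expect_equal(one$n_clusters, 1)
  for (ms in list(all_single, one)) {
    expect_true(ms$n_clusters >= 1 && ms$n_clusters <= 30)
    expect_equal(sum(ms$sizes), 30)
  }
})

test_that("partitions are invariant under point relabeling", {
  set.seed(12)
  X <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
             matrix(rnorm(40, 4, 0.3), 20, 2))
  ms <- mean_shift(X, D = 0.4)
  perm <- sample(nrow(X))
  ms2 <- mean_shift(X[perm, ], D = 0.4)
  expect_same_partition(ms$labels[perm], ms2$labels)
})

test_that("converged modes are fixed points of the update", {
  set.seed(13)
  X <- rbind(matrix(rnorm(60, 0, 0.05), 30, 2),
             matrix(rnorm(60, c(3, 1), 0.05), 30, 2))
  nc <- normalize_points(X)
  ms <- mean_shift(nc, D = 0.3, ell = 0.2, tol = 1e-8, max_iter = 500)
  # apply one update by hand from each reported mode against the data
  for (c in seq_len(ms$n_clusters)) {
    m0 <- ms$modes_normalized[c, ]
    d <- sqrt(colSums((t(nc$points) - m0)^2))
    w <- kernel_weight(d, "gaussian", D = 0.3, ell = 0.2)
    m1 <- colSums(nc$points * w) / sum(w)
    expect_lt(sqrt(sum((m1 - m0)^2)), 1e-6)
  }
})

test_that("law of total variance holds for any assignment", {
  set.seed(14)
  X <- matrix(rnorm(300), 100, 3)
  ms <- mean_shift(X, D = 0.5)
  K <- nrow(X)
  for (j in 1:3) {
    tot <- mean(X[, j]^2) - mean(X[, j])^2
    within <- sum(ms$sizes * ms$cluster_sigma[, j]^2)
    between <- sum(ms$sizes * (ms$cluster_mean[, j] - mean(X[, j]))^2)
    expect_equal(within + between, K * tot, tolerance = 1e-10 * K * tot)
  }
})

test_that("cluster_sigma reports population scales with a floor", {
  X <- cbind(c(0, 2, 10, 10))
  lab <- c(1, 1, 2, 2)
  expect_equal(cluster_sigma(X, lab, 1)[1], 1)           # {0,2}: sd = 1
  # a single cluster over all points equals the global population sd
  expect_equal(cluster_sigma(X, rep(1, 4), 1)[1],
               sqrt(mean(X^2) - mean(X)^2))
  # singleton cluster: floored, nonzero
  s <- cluster_sigma(cbind(c(0, 5, 9)), c(1, 2, 2), 1,
                     lower = 0, upper = 10)
  expect_gt(s[1], 0)
  expect_equal(s[1], 1e-12 * 10)
  expect_error(cluster_sigma(X, lab, 99), "unknown")
})

test_that("compiled mean shift matches the brute-force reference exactly", {
  set.seed(15)
  for (rep in 1:25) {
    J <- sample(2:3, 1)
    K <- sample(20:120, 1)
    centers <- matrix(runif(J * 3, 0, 1), 3, J)
    X <- centers[sample(3, K, replace = TRUE), ] +
      matrix(rnorm(K * J, 0, 0.04), K, J)
    nc <- normalize_points(X)
    for (blur in c(FALSE, TRUE)) {
      ms <- mean_shift(nc, kernel = "gaussian", D = 0.35, ell = 0.15,
                       blurring = blur)
      ref <- reference_mean_shift(nc$points, kernel = "gaussian", D = 0.35,
                                  ell = 0.15, blurring = blur)
      expect_same_partition(ms$labels, ref)
    }
  }
})
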