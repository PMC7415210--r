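test_that("exemplar selection follows the L1-norm deviation rule", {
  # identical windows: zero spread, empty selection with a warning
  w <- as_windowed(matrix(0.5, 20, 6), 4)
  expect_warning(ex <- select_exemplars(list(w)), "identical")
  expect_length(ex$indices[[1]], 0)

  # windows with inflated edge magnitudes are selected
  set.seed(8)
  base <- matrix(rnorm(126 * 10, sd = 0.05), 126, 10)
  hot <- sample(126, 10)
  base[hot, ] <- base[hot, ] * 3 + 0.5
  w <- as_windowed(base, 5)
  ex <- select_exemplars(list(w), threshold_sd = 1.5)
  expect_true(all(hot %in% ex$indices[[1]]))

  # hand-coded selector agrees exactly
  l <- rowSums(abs(base))
  m <- sum(abs(colMeans(base)))
  expect_equal(ex$indices[[1]], which(abs(l - m) > 1.5 * sd(l)))

  # threshold 0 selects every window whose norm differs from the reference
  ex0 <- select_exemplars(list(w), threshold_sd = 0)
  expect_equal(ex0$indices[[1]], which(l != m))
})

test_that("kmedians_l1 finds the exact solution on separable 1-D data", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  fit <- best_kmedians(x, 2)
  expect_equal(fit$cost, 2)
  expect_equal(sort(as.numeric(fit$centroids)), c(0.5, 10.5))
  expect_equal(fit$labels[1], fit$labels[2])
  expect_equal(fit$labels[3], fit$labels[4])
  expect_false(fit$labels[1] == fit$labels[3])
})

test_that("kmedians_l1 honors its contracts", {
  set.seed(10)
  x <- matrix(rnorm(40 * 3), 40, 3)
  # k = 1: centroid is the element-wise median
  f1 <- kmedians_l1(x, 1)
  expect_equal(as.numeric(f1$centroids), apply(x, 2, median))

  # fixed point: data at k distinct points, init there -> cost 0, 1 update
  pts <- matrix(c(0, 0, 5, 5, 9, 1), 3, 2, byrow = TRUE)
  x2 <- pts[rep(1:3, each = 4), ]
  f2 <- kmedians_l1(x2, 3, init = pts)
  expect_equal(f2$cost, 0)
  expect_lte(f2$iterations, 1)
  expect_equal(f2$labels, rep(1:3, each = 4))

  # k exceeding distinct vectors is an error
  expect_error(kmedians_l1(x2, 4), "distinct")

  # assignment ties break toward the lowest centroid index
  xt <- matrix(c(0, 1), ncol = 1)
  ft <- kmedians_l1(matrix(0.5), 1, init = matrix(0.5))
  expect_equal(ft$labels, 1L)
  xx <- matrix(c(0.5, 0.5), 2, 1)
  f_tie <- dynfc:::cpp_kmedians(xx, t(xx), matrix(c(0, 1), 2, 1), 0L, 0)
  expect_equal(f_tie$labels, c(0L, 0L))  # centroids equidistant -> lowest index
})

test_that("kmedians_l1 matches the brute-force partition optimum", {
  set.seed(11)
  for (trial in 1:12) {
    n <- sample(5:8, 1)
    k <- sample(2:3, 1)
    d <- sample(1:3, 1)
    x <- matrix(round(rnorm(n * d), 2), n, d)
    expect_equal(best_kmedians(x, k)$cost, brute_force_kmedians_cost(x, k),
                 tolerance = 1e-9,
                 label = sprintf("trial %d (n=%d k=%d d=%d)", trial, n, k, d))
  }
})

test_that("clustering cost is non-increasing across iterations", {
  set.seed(12)
  x <- matrix(rnorm(200 * 8), 200, 8)
  init <- x[1:4, ]
  costs <- vapply(1:12, function(it) {
    dynfc:::cpp_kmedians(x, t(x), init, it, 0)$cost
  }, numeric(1))
  expect_true(all(diff(costs) <= 1e-10))
})

test_that("model selection recovers the number of separated blobs", {
  set.seed(13)
  blobs <- rbind(matrix(rnorm(60, 0, 0.3), 30, 2),
                 matrix(rnorm(60, 5, 0.3), 30, 2),
                 cbind(rnorm(30, 0, 0.3), rnorm(30, 6, 0.3)))
  ms <- evaluate_k_range(blobs, 2, 6, replicates = 20, seed = 3)
  expect_equal(as.integer(ms$chosen_k), 3)
  expect_equal(which.max(ms$curves$ch), match(3, ms$curves$k))

  # restricting the scan still picks 3
  ms2 <- evaluate_k_range(blobs, 2, 3, replicates = 20, seed = 3)
  expect_equal(as.integer(ms2$chosen_k), 3)

  # a single high-dimensional blob has no cluster structure
  set.seed(14)
  blob <- matrix(rnorm(120 * 60), 120, 60)
  expect_warning(evaluate_k_range(blob, 2, 4, replicates = 10, seed = 4),
                 "no cluster structure")
})

test_that("internal validity indices agree with reference implementations", {
  set.seed(17)
  x <- rbind(matrix(rnorm(40, 0, 1), 20, 2),
             matrix(rnorm(40, 3, 1), 20, 2))
  lab <- rep(1:2, each = 20)

  skip_if_not_installed("cluster")
  d <- dynfc:::cpp_pairwise_l1(x)
  sil_ref <- mean(cluster::silhouette(lab, dmatrix = d)[, "sil_width"])
  expect_equal(dynfc:::silhouette_mean(d, lab), sil_ref, tolerance = 1e-12)

  skip_if_not_installed("mclust")
  set.seed(18)
  for (r in 1:5) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:4, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("choose_k returns the CH argmax with tie-break to lowest k", {
  ms <- structure(list(curves = data.frame(k = 2:4,
                                           silhouette = c(0.2, 0.5, 0.4),
                                           ch = c(10, 50, 20),
                                           cost = c(3, 2, 1))),
                  class = "model_selection")
  expect_equal(as.integer(choose_k(ms)), 3)

  flat <- structure(list(curves = data.frame(k = 2:4,
                                             silhouette = c(0.1, 0.1, 0.1),
                                             ch = c(5, 5, 5),
                                             cost = c(3, 2, 1))),
                    class = "model_selection")
  expect_warning(kf <- choose_k(flat), "flat")
  expect_equal(as.integer(kf), 2)
})

test_that("k_max beyond the exemplar count truncates the range", {
  x <- matrix(c(0, 0, 1, 1, 5, 5, 6, 6), 4, 2, byrow = TRUE)
  expect_warning(ms <- evaluate_k_range(x, 2, 9, replicates = 5, seed = 1),
                 "truncating")
  expect_lte(max(ms$curves$k), 4)
})

test_that("final clustering relabels states by ascending strength and is
           invariant to participant order", {
  set.seed(15)
  weak <- matrix(rnorm(30 * 6, 0, 0.05), 30, 6)
  strong <- matrix(rnorm(30 * 6, 0.8, 0.05), 30, 6)
  w1 <- as_windowed(rbind(weak, strong), 4, id = "a")
  w2 <- as_windowed(rbind(strong, weak), 4, id = "b")
  init <- rbind(colMeans(strong), colMeans(weak))  # deliberately reversed
  model <- final_clustering(list(w1, w2), init)

  # state 1 must be the weak state regardless of init order
  expect_lt(model$strength[1], model$strength[2])
  expect_equal(model$labels[["a"]], rep(c(1L, 2L), each = 30))
  expect_equal(model$labels[["b"]], rep(c(2L, 1L), each = 30))

  # permuting participants permutes labels identically
  model2 <- final_clustering(list(w2, w1), init)
  expect_equal(model2$labels[["a"]], model$labels[["a"]])
  expect_equal(model2$centroids, model$centroids)

  # relabeling is a pure permutation: memberships unchanged
  expect_equal(adjusted_rand_index(model$labels_flat,
                                   c(rep(1:2, each = 30),
                                     rep(2:1, each = 30))), 1)
})

test_that("initializing at the optimum reproduces a planted partition", {
  set.seed(16)
  c1 <- rnorm(12)
  c2 <- rnorm(12) + 3
  x <- rbind(matrix(rep(c1, 25), 25, byrow = TRUE) + rnorm(300, 0, 0.1),
             matrix(rep(c2, 25), 25, byrow = TRUE) + rnorm(300, 0, 0.1))
  init <- rbind(apply(x[1:25, ], 2, median), apply(x[26:50, ], 2, median))
  fit <- kmedians_l1(x, 2, init = init)
  expect_equal(fit$labels, rep(1:2, each = 25))
})
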