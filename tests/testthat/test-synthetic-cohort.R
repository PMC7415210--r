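test_that("build_state_correlation produces the requested block pattern", {
  # zero correlation levels force the identity
  expect_equal(build_state_correlation(c(1, 1, 2, 2), 0, 0), diag(4))

  # two modules of two regions: off-diagonals are exactly {0.6, 0.1}, PSD
  m <- build_state_correlation(c(1, 1, 2, 2), 0.6, 0.1)
  expect_equal(diag(m), rep(1, 4))
  expect_equal(m[1, 2], 0.6)
  expect_equal(m[3, 4], 0.6)
  expect_equal(m[1, 3], 0.1)
  expect_true(isSymmetric(m))
  expect_gte(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), -1e-10)

  # equicorrelation with r > -1/(n-1) is PSD without repair
  eq <- build_state_correlation(rep(1, 10), 0.99, 0)
  expect_equal(unique(vectorize_upper(eq)), 0.99)
  expect_gte(min(eigen(eq, symmetric = TRUE, only.values = TRUE)$values), -1e-10)

  expect_error(build_state_correlation(c(1, 2), 1, 0), "\\(-1, 1\\)")
})

test_that("infeasible block designs are repaired to a PSD correlation", {
  # strongly negative equicorrelation is infeasible; projection must return a
  # valid correlation matrix
  m <- build_state_correlation(rep(1, 8), -0.5, 0)
  expect_equal(diag(m), rep(1, 8))
  expect_gte(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_true(all(abs(m) <= 1 + 1e-12))
})

test_that("sample_state_sequence follows the Markov chain", {
  # absorbing chain stays put
  s <- sample_state_sequence(diag(3), 50, initial_distribution = c(0, 1, 0))
  expect_equal(s, rep(2, 50))

  # deterministic two-state cycle alternates strictly
  flip <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  s <- sample_state_sequence(flip, 10, initial_distribution = c(1, 0))
  expect_equal(s, rep(c(1, 2), 5))

  # long-run empirical transition frequencies match the specified rows
  set.seed(41)
  p <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  s <- sample_state_sequence(p, 20000)
  emp <- prop.table(table(s[-length(s)], s[-1]), margin = 1)
  expect_lt(max(abs(emp - p)), 0.01)

  expect_error(sample_state_sequence(matrix(c(0.5, 0.4, 0.1, 0.9), 2, 2),
                                     10),
               "sum to 1")
})

test_that("generate_cohort is byte-deterministic under a fixed seed", {
  cfg <- generator_config(n_per_group = 2, n_regions = 10, n_timepoints = 30,
                          seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(cfg, d1)
  generate_cohort(cfg, d2)
  f1 <- list.files(d1)
  expect_setequal(f1, c(sprintf("sub%03d.tsv", 1:4), "manifest.csv",
                        "truth.json"))
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = paste("md5 of", f))
  }
})

test_that("noise-free single-state series reproduce the truth correlation", {
  cfg <- generator_config(n_per_group = 1, n_regions = 15,
                          n_timepoints = 10000, n_states = 1,
                          observation_noise_sd = 0, seed = 3)
  res <- generate_cohort(cfg, withr::local_tempdir())
  ts <- load_roi_timeseries(file.path(res$dir, "sub001.tsv"))
  expect_lt(max(abs(cor(ts$x) - res$truth$state_corr$control[[1]])), 0.05)
  expect_true(all(is.finite(ts$x)))
})

test_that("planted patient edge effects raise that edge's windowed FC", {
  eff <- list(list(i = 1, j = 2, state = 2, delta_r = 0.3))
  cfg <- generator_config(n_per_group = 20, n_regions = 20,
                          patient_edge_effects = eff, seed = 19)
  res <- generate_cohort(cfg, withr::local_tempdir())
  w <- cohort_windows(res$dir, res$manifest)
  e12 <- dynfc:::edge_index(1, 2, 20)

  # mean windowed FC on the planted edge, over windows purely in state 2
  group_means <- vapply(c("control", "patient"), function(g) {
    ids <- res$manifest$id[res$manifest$group == g]
    vals <- unlist(lapply(ids, function(id) {
      i <- match(id, res$manifest$id)
      wl <- pure_window_labels(res$truth$sequences[[id]])
      w[[i]]$edges[which(wl == 2), e12]
    }))
    mean(vals)
  }, numeric(1))
  expect_gt(group_means["patient"], group_means["control"])
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(patient_edge_effects =
                                  list(list(i = 1, j = 99, state = 1,
                                            delta_r = 0.1))),
               "absent edge")
  bad <- matrix(c(0.5, 0.6, 0.1, 0.9), 2, 2, byrow = TRUE)
  expect_error(generator_config(n_states = 2, transition_control = bad),
               "sum to 1")
})
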