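test_that("normality gate routes distributions to the right test family", {
  set.seed(60)
  normal_calls <- vapply(1:50, function(i) {
    normality_gate(rnorm(200)) == "normal"
  }, logical(1))
  expect_gte(mean(normal_calls), 0.9)

  uniform_calls <- vapply(1:50, function(i) {
    normality_gate(runif(500)) == "non-normal"
  }, logical(1))
  expect_gte(mean(uniform_calls), 0.9)

  expect_warning(g <- normality_gate(rep(1, 10)), "constant")
  expect_equal(as.character(g), "non-normal")
  expect_error(normality_gate(c(1, 2, 3)), "at least 5")
})

test_that("bh_fdr reproduces the hand-coded step-up procedure", {
  fdr <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_equal(sum(fdr$reject), 3)
  expect_equal(sum(fdr$reject),
               bh_rejections_oracle(c(0.01, 0.02, 0.03, 0.5), 0.05))

  expect_equal(sum(bh_fdr(rep(1, 10))$reject), 0)
  expect_true(bh_fdr(0.04, q = 0.05)$reject)

  set.seed(61)
  for (r in 1:10) {
    p <- runif(50)^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    fdr <- bh_fdr(p, q)
    expect_equal(sum(fdr$reject), bh_rejections_oracle(p, q))
    expect_true(all(fdr$adjusted >= p - 1e-12))
    # monotone in q: rejections grow with the level
    expect_lte(sum(bh_fdr(p, 0.01)$reject), sum(bh_fdr(p, 0.1)$reject))
  }
  expect_error(bh_fdr(c(0.1, NA)), "finite")
})

test_that("edgewise GLM reduces to the pooled t-test without covariates", {
  set.seed(62)
  p <- 6
  n <- 16
  wfc <- lapply(1:n, function(i) random_windowed(30, p, seed = 100 + i,
                                                 id = sprintf("s%02d", i)))
  sfc <- lapply(wfc, function(w) participant_state_fc(w, rep(1L, n_windows(w)),
                                                      k = 1))
  manifest <- data.frame(id = sprintf("s%02d", 1:n),
                         group = rep(c("control", "patient"), each = n / 2),
                         age = rep(70, n), sex = rep("F", n))
  res <- edgewise_glm(sfc, manifest, state = 1)
  y <- do.call(rbind, lapply(sfc, function(s) s$edge_medians[[1]]))
  for (e in c(1, 7, ncol(y))) {
    t_oracle <- pooled_t_oracle(y[manifest$group == "patient", e],
                                y[manifest$group == "control", e])
    expect_equal(res$t[e], t_oracle, tolerance = 1e-10)
  }
  expect_true(all(res$p_fdr >= res$p - 1e-12))
  expect_equal(res$direction[res$beta > 0][1], "patient>control")

  # participant order must not matter
  perm <- sample(n)
  res2 <- edgewise_glm(sfc[perm], manifest, state = 1)
  expect_equal(res2$t, res$t, tolerance = 1e-12)

  # a state with fewer than 2 participants per group is skipped
  sfc_rare <- sfc
  for (i in 2:n) sfc_rare[[i]]$counts <- c(0L)
  expect_warning(r <- edgewise_glm(sfc_rare, manifest, state = 1), "skipped")
  expect_null(r)
})

test_that("adjusted rank test reduces to Mann-Whitney and matches the exact
           enumeration", {
  a <- c(1, 2, 3)
  b <- c(10, 11, 12)
  rt <- adjusted_rank_test(c(a, b), rep(c("g1", "g2"), each = 3))
  expect_equal(rt$U, 0)
  expect_equal(rt$p, 0.1)  # 2 * 1/20, exact two-sided

  set.seed(63)
  v <- rnorm(30)
  g <- rep(c("control", "patient"), 15)
  rt2 <- adjusted_rank_test(v, g)
  wt <- wilcox.test(v[g == "control"], v[g == "patient"])
  expect_equal(rt2$p, wt$p.value)

  # residualizing on a covariate that fully explains the values leaves noise:
  # rejection rate stays near the nominal level
  set.seed(64)
  rej <- vapply(1:200, function(i) {
    age <- runif(40, 60, 90)
    val <- 2 * age + rnorm(40)
    g <- rep(c("control", "patient"), each = 20)
    adjusted_rank_test(val, g, data.frame(age = age))$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.11)

  expect_error(adjusted_rank_test(v, g, data.frame(a = rep(1, 30),
                                                   b = rep(2, 30))),
               "singular")
})

test_that("roc_auc follows the rank formulation with tie credit", {
  expect_equal(as.numeric(roc_auc(c(5, 6, 1, 2), c("patient", "patient",
                                                   "control", "control"))), 1)
  expect_equal(as.numeric(roc_auc(rep(3, 6), rep(c("patient", "control"),
                                                 3))), 0.5)
  auc <- roc_auc(c(0.9, 0.8, 0.85, 0.7),
                 c("patient", "patient", "control", "control"))
  expect_equal(as.numeric(auc), 0.75)

  # orientation flips so the reported AUC is always >= 0.5
  flipped <- roc_auc(c(1, 2, 10, 11), c("patient", "patient", "control",
                                        "control"))
  expect_equal(as.numeric(flipped), 1)
  expect_equal(attr(flipped, "orientation"), "positive<negative")

  # invariant to strictly increasing transforms
  set.seed(65)
  s <- rnorm(30)
  lab <- rep(c("patient", "control"), 15)
  expect_equal(as.numeric(roc_auc(exp(s), lab)),
               as.numeric(roc_auc(s, lab)))

  # agreement with an established ROC implementation
  skip_if_not_installed("pROC")
  praw <- suppressMessages(pROC::auc(pROC::roc(lab, s, direction = "<",
                                               levels = c("control",
                                                          "patient"))))
  expect_equal(attr(roc_auc(s, lab), "auc_raw"), as.numeric(praw),
               tolerance = 1e-12)

  expect_error(roc_auc(1:3, rep("patient", 3)), "both classes")
})

test_that("median significant strength summarizes the planted edge set", {
  set.seed(66)
  wfc <- lapply(1:4, function(i) random_windowed(30, 5, seed = 200 + i,
                                                 id = paste0("s", i)))
  sfc <- lapply(wfc, function(w) participant_state_fc(w, rep(1L, n_windows(w)),
                                                      k = 1))
  edges <- data.frame(i = c(1, 2, 3), j = c(2, 4, 5))
  ms <- median_significant_strength(sfc, edges, state = 1)
  idx <- dynfc:::edge_index(edges$i, edges$j, 5)
  expect_equal(unname(ms[1]), median(sfc[[1]]$edge_medians[[1]][idx]))

  one <- median_significant_strength(sfc, edges[1, ], state = 1)
  expect_equal(unname(one[2]), sfc[[2]]$edge_medians[[1]][idx[1]])

  expect_equal(unname(median_significant_strength(
    list(structure(list(id = "a", counts = 1L,
                        matrices = list(diag(3)),
                        edge_medians = list(c(0.1, 0.3, 0.8))),
                   class = "participant_state_fc")),
    data.frame(i = c(1, 1, 2), j = c(2, 3, 3)), 1)), 0.3)

  expect_error(median_significant_strength(sfc, edges[0, ], 1), "empty")
})

test_that("partial correlation residualizes on covariates correctly", {
  set.seed(67)
  x <- rnorm(50)
  y <- 2 * x + rnorm(50, sd = 0.5)

  # no covariates: plain Pearson, matching cor.test
  pc <- partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate))
  expect_equal(pc$p, ct$p.value, tolerance = 1e-12)

  # y = x exactly: r = 1 whatever the (non-collinear) covariates
  z <- rnorm(50)
  expect_equal(partial_correlation(x, x, data.frame(z = z))$r, 1)

  # variables linked only through a covariate decorrelate after adjustment
  set.seed(68)
  rs <- vapply(1:40, function(i) {
    c <- rnorm(200)
    a <- c + rnorm(200)
    b <- c + rnorm(200)
    partial_correlation(a, b, data.frame(c = c))$r
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.1)

  expect_error(partial_correlation(x, y, data.frame(a = x, b = x)),
               "singular")
})

test_that("demographics table reports the conventional tests", {
  set.seed(69)
  manifest <- data.frame(
    id = sprintf("s%02d", 1:20),
    group = rep(c("control", "patient"), each = 10),
    age = round(rnorm(20, 75, 5), 1),
    sex = rep(c("M", "F"), 10),
    MMSE = c(rep(29, 10), rep(21, 10)),
    NPI = c(rep(0.5, 10), rep(5, 10)))
  tab <- demographics_table(manifest)
  expect_setequal(tab$variable, c("age", "MMSE", "NPI", "sex"))

  # identical group compositions: chi-square statistic 0, p = 1
  expect_equal(tab$p[tab$variable == "sex"], 1)
  # constant difference in MMSE: strongly significant
  expect_lt(tab$p[tab$variable == "MMSE"], 1e-3)

  # the t-test p agrees with the hand-coded Welch formula
  a <- manifest$age[manifest$group == "patient"]
  b <- manifest$age[manifest$group == "control"]
  expect_equal(tab$p[tab$variable == "age"], welch_p_oracle(a, b),
               tolerance = 1e-10)

  expect_error(demographics_table(manifest[manifest$group == "control", ]),
               "empty")
})

test_that("scalar tests hold their level on null data", {
  # adjusted rank test and partial correlation, each on independent null
  # draws with age/sex covariates present
  set.seed(70)
  n <- 52
  rej_rank <- logical(500)
  rej_pcor <- logical(500)
  for (i in 1:500) {
    g <- rep(c("control", "patient"), each = n / 2)
    cov <- data.frame(age = rnorm(n, 75, 6), sex = rbinom(n, 1, 0.5))
    v <- rnorm(n)
    rej_rank[i] <- adjusted_rank_test(v, g, cov)$p < 0.05
    rej_pcor[i] <- partial_correlation(rnorm(n), rnorm(n), cov)$p < 0.05
  }
  expect_gte(mean(rej_rank), 0.03)
  expect_lte(mean(rej_rank), 0.07)
  expect_gte(mean(rej_pcor), 0.03)
  expect_lte(mean(rej_pcor), 0.07)
})
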