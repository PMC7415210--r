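# exhaustive k-medians oracle: minimum cost over all assignments of n vectors
# to k clusters, centroid = element-wise median of members
brute_force_kmedians_cost <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n <= 10)
  assignments <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (r in seq_len(nrow(assignments))) {
    lab <- assignments[r, ]
    cost <- 0
    for (g in unique(lab)) {
      xi <- x[lab == g, , drop = FALSE]
      med <- apply(xi, 2, median)
      cost <- cost + sum(abs(sweep(xi, 2, med)))
    }
    if (cost < best) best <- cost
  }
  best
}

# best kmedians_l1 over many initializations: every k-subset of distinct
# rows plus seeded random-partition medians (Lloyd descends from each)
best_kmedians <- function(x, k, partition_restarts = 200) {
  x <- as.matrix(x)
  ux <- unique(x)
  combos <- combn(nrow(ux), k)
  best <- NULL
  consider <- function(fit) {
    if (is.null(best) || fit$cost < best$cost) best <<- fit
  }
  for (c in seq_len(ncol(combos))) {
    consider(kmedians_l1(x, k, init = ux[combos[, c], , drop = FALSE]))
  }
  for (r in seq_len(partition_restarts)) {
    lab <- sample.int(k, nrow(x), replace = TRUE)
    lab[sample(nrow(x), k)] <- seq_len(k)  # all clusters nonempty
    init <- do.call(rbind, lapply(seq_len(k), function(g) {
      apply(x[lab == g, , drop = FALSE], 2, median)
    }))
    if (anyDuplicated(init)) next
    consider(kmedians_l1(x, k, init = init))
  }
  best
}

# hand-coded Benjamini-Hochberg step-up: number of rejections at level q
bh_rejections_oracle <- function(p, q) {
  m <- length(p)
  ord <- sort(p)
  passed <- which(ord <= seq_len(m) * q / m)
  if (length(passed) == 0) 0 else max(passed)
}

# two-sample t statistics from the textbook formulas
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}
welch_t_oracle <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}
welch_p_oracle <- function(a, b) {
  t <- welch_t_oracle(a, b)
  v1 <- var(a) / length(a); v2 <- var(b) / length(b)
  df <- (v1 + v2)^2 / (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
  2 * pt(-abs(t), df)
}
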