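#' Select high-variance exemplar windows per participant
#'
#' For each participant, let `l_i` be the L1-norm (sum of absolute edge
#' values) of window `i` and `m` the L1-norm of the participant's
#' across-window mean matrix. Windows with `|l_i - m| > threshold_sd * s`,
#' where `s` is the standard deviation of the `l_i`, are selected as
#' exemplars. The deviation is two-sided and the SD is the participant's own,
#' so subsampling is performed participant by participant. Norms are taken
#' over the unique off-diagonal edges.
#'
#' @param wfc_list list of `windowed_fc`, one per participant.
#' @param threshold_sd selection threshold in SD units (default 1.5).
#' @return object of class `exemplar_set` with fields `indices`
#'   (per-participant selected window indices), `vectors` (stacked edge
#'   vectors of selected windows), `participant` (participant id per row),
#'   `threshold_sd`.
#' @export
select_exemplars <- function(wfc_list, threshold_sd = 1.5) {
  indices <- vector("list", length(wfc_list))
  names(indices) <- vapply(wfc_list, `[[`, "", "id")
  rows <- list()
  who <- character(0)
  for (i in seq_along(wfc_list)) {
    wfc <- wfc_list[[i]]
    if (n_windows(wfc) < 2) stop("need at least 2 windows per participant")
    l <- rowSums(abs(wfc$edges))
    m <- sum(abs(colMeans(wfc$edges)))
    s <- sd(l)
    if (is.na(s) || s == 0) {
      warning("all windows identical for participant ", wfc$id,
              "; no exemplars selected")
      sel <- integer(0)
    } else {
      sel <- which(abs(l - m) > threshold_sd * s)
    }
    indices[[i]] <- sel
    if (length(sel) > 0) {
      rows[[length(rows) + 1]] <- wfc$edges[sel, , drop = FALSE]
      who <- c(who, rep(wfc$id, length(sel)))
    }
  }
  vectors <- if (length(rows)) do.call(rbind, rows) else
    matrix(0, 0, ncol(wfc_list[[1]]$edges))
  structure(list(indices = indices, vectors = vectors, participant = who,
                 threshold_sd = threshold_sd),
            class = "exemplar_set")
}

#' k-means clustering under the L1 (cityblock) distance
#'
#' Lloyd-style alternation in which each centroid is updated to the
#' element-wise median of its members — the L1-consistent centroid — and each
#' vector is assigned to the nearest centroid by L1 distance, ties broken
#' toward the lowest centroid index. Stops when labels are unchanged, the
#' cost decrease falls below `tol`, or `max_iter` is reached; the cost
#' (sum of L1 distances to assigned centroids) is non-increasing across
#' iterations. An emptied cluster is re-seeded at the vector farthest from
#' its current centroid.
#'
#' @param x numeric matrix, one vector per row.
#' @param k number of clusters.
#' @param init optional `k x ncol(x)` initial centroid matrix; when missing,
#'   `k` distinct rows are sampled using the current RNG.
#' @param max_iter,tol stopping controls; the default `tol = 0` stops on
#'   label stability alone (the cost-decrease stop engages for `tol > 0`).
#' @param xt optional pre-transposed copy of `x` (an optimization for
#'   callers running many restarts on the same data).
#' @return list with `labels` (1..k), `centroids`, `cost`, `iterations`
#'   (number of centroid updates), `reseeds`.
#' @export
kmedians_l1 <- function(x, k, init = NULL, max_iter = 100, tol = 0,
                        xt = NULL) {
  x <- as.matrix(x)
  if (is.null(xt)) xt <- t(x)
  if (is.null(init)) {
    init <- sample_distinct_rows(x, k)
  } else {
    init <- as.matrix(init)
    if (nrow(init) != k || ncol(init) != ncol(x)) {
      stop("init must be a k x ncol(x) matrix")
    }
  }
  res <- cpp_kmedians(x, xt, init, as.integer(max_iter), tol)
  list(labels = res$labels + 1L, centroids = res$centroids, cost = res$cost,
       iterations = res$iterations, reseeds = res$reseeds)
}

# sample k pairwise-distinct rows for initialization; full row
# deduplication only as a fallback (it is expensive on wide matrices)
sample_distinct_rows <- function(x, k, tries = 100) {
  n <- nrow(x)
  if (k > n) stop("k = ", k, " exceeds the number of distinct vectors (",
                  n, ")")
  for (t in seq_len(tries)) {
    idx <- sample.int(n, k)
    cand <- x[idx, , drop = FALSE]
    if (k == 1 || !anyDuplicated(cand)) return(cand)
  }
  ux <- unique(x)
  if (k > nrow(ux)) {
    stop("k = ", k, " exceeds the number of distinct vectors (", nrow(ux), ")")
  }
  ux[sample.int(nrow(ux), k), , drop = FALSE]
}

# mean silhouette width from a precomputed distance matrix
silhouette_mean <- function(d, labels) {
  n <- length(labels)
  ks <- sort(unique(labels))
  if (length(ks) < 2) return(NA_real_)
  sizes <- table(factor(labels, levels = ks))
  s <- numeric(n)
  for (i in seq_len(n)) {
    if (sizes[[as.character(labels[i])]] == 1) {
      s[i] <- 0
      next
    }
    means <- vapply(ks, function(g) {
      idx <- which(labels == g)
      idx <- setdiff(idx, i)
      mean(d[i, idx])
    }, numeric(1))
    a <- means[match(labels[i], ks)]
    b <- min(means[ks != labels[i]])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Calinski-Harabasz index (variance-ratio criterion, Euclidean on means)
calinski_harabasz <- function(x, labels) {
  n <- nrow(x)
  ks <- sort(unique(labels))
  k <- length(ks)
  if (k < 2) return(NA_real_)
  overall <- colMeans(x)
  b <- 0
  w <- 0
  for (g in ks) {
    xi <- x[labels == g, , drop = FALSE]
    ci <- colMeans(xi)
    b <- b + nrow(xi) * sum((ci - overall)^2)
    w <- w + sum(sweep(xi, 2, ci)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

#' Scan a range of cluster numbers on the exemplar windows
#'
#' For each `k` in the scanned range, the L1 k-means procedure is repeated
#' `replicates` times from random initializations (seeds derived from the
#' master seed) and the lowest-cost replicate is scored by the mean
#' Silhouette width (L1 metric) and the Calinski-Harabasz index.
#'
#' Restarts are screened: every replicate's initial centroid set is scored
#' by its exact assignment cost, and the `keep` most promising restarts are
#' run to convergence; the best-cost converged fit is scored. This preserves
#' the best-of-restarts semantics at a fraction of the computation.
#'
#' @param vectors matrix of exemplar edge vectors (or an `exemplar_set`).
#' @param k_min,k_max scanned range (defaults 2..9).
#' @param replicates seeded restarts per `k` (default 100).
#' @param seed master seed for replicate initializations.
#' @param keep number of screened restarts run to convergence (default 5).
#' @param max_iter,tol convergence controls for the kept restarts.
#' @return object of class `model_selection`: data frame `curves` with
#'   columns `k`, `silhouette`, `ch`, `cost`, plus `chosen_k`,
#'   `silhouette_elbow_k`, `agree`, `best` (per-k best clustering),
#'   `replicates`, `seed`.
#' @export
evaluate_k_range <- function(vectors, k_min = 2, k_max = 9, replicates = 100,
                             seed = 1L, keep = 5, max_iter = 30, tol = 0) {
  if (inherits(vectors, "exemplar_set")) vectors <- vectors$vectors
  x <- as.matrix(vectors)
  xt <- t(x)
  n_distinct <- if (nrow(x) <= 1000) nrow(unique(x)) else nrow(x)
  if (k_max > n_distinct) {
    warning("k_max = ", k_max, " exceeds the number of distinct vectors (",
            n_distinct, "); truncating the range")
    k_max <- n_distinct
  }
  if (k_min > k_max) stop("empty k range after truncation")
  ks <- k_min:k_max

  d <- cpp_pairwise_l1(x)
  set.seed(seed)
  rep_seeds <- matrix(draw_subseeds(length(ks) * replicates),
                      nrow = length(ks))

  curves <- data.frame(k = ks, silhouette = NA_real_, ch = NA_real_,
                       cost = NA_real_)
  best <- vector("list", length(ks))
  for (a in seq_along(ks)) {
    k <- ks[a]
    inits <- vector("list", replicates)
    screen_cost <- numeric(replicates)
    for (r in seq_len(replicates)) {
      set.seed(rep_seeds[a, r])
      fit0 <- kmedians_l1(x, k, max_iter = 0, tol = tol, xt = xt)
      inits[[r]] <- fit0$centroids
      screen_cost[r] <- fit0$cost
    }
    fit_best <- NULL
    for (r in order(screen_cost)[seq_len(min(keep, replicates))]) {
      fit <- kmedians_l1(x, k, init = inits[[r]], max_iter = max_iter,
                         tol = tol, xt = xt)
      if (is.null(fit_best) || fit$cost < fit_best$cost) fit_best <- fit
    }
    best[[a]] <- fit_best
    curves$cost[a] <- fit_best$cost
    curves$silhouette[a] <- silhouette_mean(d, fit_best$labels)
    curves$ch[a] <- calinski_harabasz(x, fit_best$labels)
  }
  if (all(curves$silhouette < 0.02, na.rm = TRUE)) {
    warning("no cluster structure: silhouette is low across the scanned range")
  }
  ms <- structure(list(curves = curves, best = best, replicates = replicates,
                       seed = seed),
                  class = "model_selection")
  choice <- choose_k(ms)
  ms$chosen_k <- choice
  ms$silhouette_elbow_k <- attr(choice, "silhouette_elbow_k")
  ms$agree <- attr(choice, "agree")
  ms
}

#' Choose the number of states from a model-selection scan
#'
#' Returns the `k` with the peak Calinski-Harabasz index. The Silhouette
#' elbow (the interior `k` maximizing the discrete second difference of the
#' Silhouette curve) is computed alongside; when the two criteria disagree
#' the CH peak is returned and the disagreement is recorded in the result's
#' attributes. A flat CH curve falls back to the lowest `k` with a warning.
#'
#' @param selection a `model_selection`.
#' @return chosen `k` with attributes `silhouette_elbow_k` and `agree`.
#' @export
choose_k <- function(selection) {
  curves <- selection$curves
  ch <- curves$ch
  if (length(unique(ch)) == 1) {
    warning("flat Calinski-Harabasz curve; falling back to the lowest k")
    k_ch <- curves$k[1]
  } else {
    k_ch <- curves$k[which.max(ch)]
  }
  sil <- curves$silhouette
  elbow <- NA_integer_
  if (length(sil) >= 3) {
    d2 <- sil[seq_along(sil)[-c(1, length(sil))] + 1] -
      2 * sil[-c(1, length(sil))] + sil[seq_along(sil)[-c(1, length(sil))] - 1]
    elbow <- curves$k[-c(1, length(sil))][which.max(d2)]
  }
  structure(k_ch, silhouette_elbow_k = elbow,
            agree = isTRUE(elbow == k_ch))
}

#' Final clustering of all windows, seeded by exemplar centroids
#'
#' A single deterministic L1 k-means run over every window of every
#' participant, initialized at the centroids found on the exemplar subset.
#' States are then relabeled by ascending mean absolute centroid
#' connectivity, so state 1 is always the weakest ("baseline") state and the
#' naming is stable across runs.
#'
#' @param wfc_list list of `windowed_fc`, one per participant.
#' @param centroids `k x n_edges` initial centroid matrix.
#' @param max_iter,tol passed to [kmedians_l1()].
#' @return object of class `state_model` with fields `k`, `centroids`
#'   (relabeled), `labels` (per-participant list of window state labels),
#'   `labels_flat`, `participant` (id per flat row), `cost`, `iterations`,
#'   `reseeds`, `strength` (mean |centroid| per state).
#' @export
final_clustering <- function(wfc_list, centroids, max_iter = 100, tol = 1e-8) {
  x <- do.call(rbind, lapply(wfc_list, `[[`, "edges"))
  ids <- unlist(lapply(wfc_list, function(w) rep(w$id, n_windows(w))))
  k <- nrow(centroids)
  fit <- kmedians_l1(x, k, init = centroids, max_iter = max_iter, tol = tol)

  strength <- rowMeans(abs(fit$centroids))
  ord <- order(strength)                   # state 1 = weakest connectivity
  relab <- match(seq_len(k), ord)          # old label -> new label
  labels_flat <- relab[fit$labels]
  centroids_new <- fit$centroids[ord, , drop = FALSE]

  labels <- split(labels_flat, factor(ids, levels = unique(ids)))
  structure(list(k = k, centroids = centroids_new, labels = labels,
                 labels_flat = labels_flat, participant = ids,
                 cost = fit$cost, iterations = fit$iterations,
                 reseeds = fit$reseeds, strength = strength[ord]),
            class = "state_model")
}
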