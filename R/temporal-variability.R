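#' Nodal temporal variability of functional connectivity
#'
#' For region k, its FC profile in window i is row k of the window-i
#' correlation matrix with the self-entry removed. The temporal variability
#' of region k is one minus the temporal stability:
#'
#'   V_k = 1 - sum over all ordered pairs i != j of
#'         cor(profile_i, profile_j) / (n (n - 1)),
#'
#' where n is the number of windows. Pearson correlation is symmetric, so the
#' sum is evaluated over unordered pairs with the denominator handled
#' analytically; the value lies in \[0, 2\] (0 = perfectly stable profile,
#' 2 = profiles anti-correlated across windows). A region whose profile is
#' constant in any window (possible after zero-variance flagging upstream)
#' is marked invalid (NA) rather than silently propagating NaN.
#'
#' @param wfc a `windowed_fc` with at least 2 windows and 3 regions.
#' @return object of class `variability_profile` with fields `id`, `v`
#'   (named per-region values, NA when invalid), `valid` (logical mask),
#'   `n` (window count used).
#' @export
temporal_variability <- function(wfc) {
  n <- n_windows(wfc)
  p <- wfc$n_regions
  if (n < 2) stop("temporal variability needs at least 2 windows")
  if (p < 3) stop("temporal variability needs at least 3 regions")
  m <- p - 1                               # profile length
  v <- setNames(rep(NA_real_, p), wfc$region_labels)
  valid <- setNames(rep(FALSE, p), wfc$region_labels)
  for (k in seq_len(p)) {
    prof <- wfc$edges[, region_edge_indices(k, p), drop = FALSE]  # n x (p-1)
    mu <- rowMeans(prof)
    cs <- prof - mu
    ss <- rowSums(cs^2)
    if (any(ss == 0)) next                 # constant profile in some window
    z <- cs / sqrt(ss / (m - 1))
    s <- colSums(z)
    # sum over ordered pairs of cor(z_i, z_j); rows satisfy sum(z^2) = m-1
    pair_sum <- (sum(s^2) - n * (m - 1)) / (m - 1)
    v[k] <- 1 - pair_sum / (n * (n - 1))
    valid[k] <- TRUE
  }
  structure(list(id = wfc$id, v = v, valid = valid, n = n),
            class = "variability_profile")
}

#' Reference implementation of temporal variability (explicit double loop)
#'
#' Computes the same quantity as [temporal_variability()] by devectorizing
#' every window matrix and averaging `stats::cor` over all unordered window
#' pairs for each region. Independent of the vectorized path; intended for
#' verification and small inputs only (O(n^2 p) correlations).
#'
#' @param wfc a `windowed_fc`.
#' @return object of class `variability_profile`.
#' @export
variability_oracle <- function(wfc) {
  n <- n_windows(wfc)
  p <- wfc$n_regions
  if (n < 2) stop("temporal variability needs at least 2 windows")
  if (p < 3) stop("temporal variability needs at least 3 regions")
  mats <- lapply(seq_len(n), function(i) window_matrix(wfc, i))
  v <- setNames(rep(NA_real_, p), wfc$region_labels)
  valid <- setNames(rep(FALSE, p), wfc$region_labels)
  for (k in seq_len(p)) {
    profiles <- lapply(mats, function(m) m[k, -k])
    if (any(vapply(profiles, sd, numeric(1)) == 0)) next
    total <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        total <- total + cor(profiles[[i]], profiles[[j]])
      }
    }
    v[k] <- 1 - 2 * total / (n * (n - 1))
    valid[k] <- TRUE
  }
  structure(list(id = wfc$id, v = v, valid = valid, n = n),
            class = "variability_profile")
}
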