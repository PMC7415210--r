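#' Flatten the strict upper triangle of a symmetric matrix
#'
#' Edge vectors are the working representation throughout the pipeline:
#' a p x p symmetric correlation matrix becomes a length p(p-1)/2 vector of
#' unique off-diagonal entries, in row-major order
#' (1,2), (1,3), ..., (1,p), (2,3), ...
#'
#' @param m square symmetric numeric matrix.
#' @return numeric vector of length `p(p-1)/2`.
#' @seealso [devectorize_upper()]
#' @export
vectorize_upper <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("vectorize_upper() expects a square matrix")
  }
  t(m)[lower.tri(m)]
}

#' Rebuild a symmetric unit-diagonal matrix from an edge vector
#'
#' @param v edge vector as produced by [vectorize_upper()].
#' @param p number of regions; inferred from `length(v)` when missing.
#' @return p x p symmetric matrix with unit diagonal.
#' @export
devectorize_upper <- function(v, p = NULL) {
  if (is.null(p)) {
    p <- (1 + sqrt(1 + 8 * length(v))) / 2
    if (abs(p - round(p)) > 1e-9) stop("length(v) is not p(p-1)/2 for integer p")
    p <- round(p)
  }
  m <- diag(p)
  m[lower.tri(m)] <- v        # row-major upper == column-major lower of t(m)
  m <- t(m)
  m[lower.tri(m)] <- v
  t(m)
}

# row-major index of edge (i, j), i < j, among the p(p-1)/2 upper-triangle edges
edge_index <- function(i, j, p) {
  (i - 1) * p - i * (i + 1) / 2 + j
}

# indices of the p-1 edges involving region k, ordered by the other region's
# index (this is row k of the matrix with the diagonal entry removed)
region_edge_indices <- function(k, p) {
  others <- setdiff(seq_len(p), k)
  edge_index(pmin(others, k), pmax(others, k), p)
}

# data.frame of (i, j) region pairs in edge-vector order
edge_pairs <- function(p) {
  i <- rep(seq_len(p - 1), times = (p - 1):1)
  j <- unlist(lapply(seq_len(p - 1), function(a) (a + 1):p))
  data.frame(i = i, j = j)
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement between two partitions, corrected for
#' chance; 1 means identical partitions, 0 is the chance level.
#'
#' @param a,b integer label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# deterministic stream of sub-seeds below 2^31, derived from the current RNG
draw_subseeds <- function(n) {
  sample.int(.Machine$integer.max, n)
}

fmt_num <- function(x) sprintf("%.10g", x)
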