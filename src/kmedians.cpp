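// Core numerics for L1 (cityblock) k-means: assignment, median updates,
// pairwise distances. Kept in C++ because the model-selection scan repeats
// the clustering hundreds of times over thousands of window vectors with
// ~p^2/2 edge dimensions.
//
// Exactness-preserving optimizations (identical trajectory to naive Lloyd):
//  - Hamerly-style distance bounds: each point keeps an upper bound on the
//    distance to its centroid and a lower bound on the distance to every
//    other centroid; bounds are updated by centroid movement (triangle
//    inequality, valid for any metric incl. L1) and most points skip the
//    full k-way scan once assignments stabilize. Skips use strict
//    inequalities, so ties always force a scan and the lowest-index
//    tie-break stays exact.
//  - median updates only for clusters whose membership changed.
//  - the caller passes the data twice (row-major and transposed) so both
//    distance streaming and per-dimension median gathers run contiguously,
//    and no per-call transpose is needed inside the replicate loop.
#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double l1_dist(const double* x, const double* c, uword d) {
  double s0 = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0;
  uword t = 0;
  for (; t + 4 <= d; t += 4) {
    s0 += std::abs(x[t] - c[t]);
    s1 += std::abs(x[t + 1] - c[t + 1]);
    s2 += std::abs(x[t + 2] - c[t + 2]);
    s3 += std::abs(x[t + 3] - c[t + 3]);
  }
  for (; t < d; ++t) s0 += std::abs(x[t] - c[t]);
  return s0 + s1 + s2 + s3;
}

// full scan of one point against all centroids; ties to the lowest index
static void scan_point(const double* x, const mat& Ct, uword& a, double& ub,
                       double& lb) {
  const uword k = Ct.n_cols, d = Ct.n_rows;
  double best = datum::inf, second = datum::inf;
  uword bj = 0;
  for (uword j = 0; j < k; ++j) {
    double s = l1_dist(x, Ct.colptr(j), d);
    if (s < best) {
      second = best;
      best = s;
      bj = j;
    } else if (s < second) {
      second = s;
    }
  }
  a = bj;
  ub = best;
  lb = second;
}

static void full_assign(const mat& Xt, const mat& Ct, uvec& labels, vec& ub,
                        vec& lb) {
  for (uword i = 0; i < Xt.n_cols; ++i) {
    uword a;
    double u, l;
    scan_point(Xt.colptr(i), Ct, a, u, l);
    labels(i) = a;
    ub(i) = u;
    lb(i) = l;
  }
}

static double median_inplace(std::vector<double>& buf) {
  const size_t m = buf.size();
  std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
  double hi = buf[m / 2];
  if (m % 2 == 1) return hi;
  double lo = *std::max_element(buf.begin(), buf.begin() + m / 2);
  return (lo + hi) / 2.0;
}

// [[Rcpp::export]]
Rcpp::List cpp_kmedians(const arma::mat& X, const arma::mat& Xt,
                        const arma::mat& C, int max_iter, double tol) {
  mat Ct = C.t();
  const uword n = Xt.n_cols, k = Ct.n_cols, d = Xt.n_rows;
  if (X.n_rows != n || X.n_cols != d)
    Rcpp::stop("X and Xt must be transposes of each other");
  if (k == 0 || k > n) Rcpp::stop("number of centroids must be in 1..nrow(X)");
  uvec labels(n), prev(n, fill::value(n + 1)), prev_mem(n, fill::value(n + 1));
  vec ub(n), lb(n), delta(k);
  double prev_cost = datum::inf;
  int updates = 0, reseeds = 0;
  std::vector<std::vector<uword>> members(k);
  std::vector<double> buf;

  full_assign(Xt, Ct, labels, ub, lb);

  for (int it = 0; it < max_iter; ++it) {
    // empty-cluster repair: reseed at the point farthest (L1) from the
    // empty cluster's current centroid, then reassign everything
    std::vector<bool> present(k, false);
    for (uword i = 0; i < n; ++i) present[labels(i)] = true;
    for (int guard = 0; guard < (int)k; ++guard) {
      bool had_empty = false;
      for (uword j = 0; j < k; ++j) {
        if (!present[j]) {
          vec dist(n);
          for (uword i = 0; i < n; ++i)
            dist(i) = l1_dist(Xt.colptr(i), Ct.colptr(j), d);
          Ct.col(j) = Xt.col(dist.index_max());
          had_empty = true;
          ++reseeds;
        }
      }
      if (!had_empty) break;
      full_assign(Xt, Ct, labels, ub, lb);
      present.assign(k, false);
      for (uword i = 0; i < n; ++i) present[labels(i)] = true;
    }

    if (all(labels == prev)) break;
    if (tol > 0) {  // optional cost-decrease stop (one exact pass per iter)
      double cost_now = 0.0;
      for (uword i = 0; i < n; ++i)
        cost_now += l1_dist(Xt.colptr(i), Ct.colptr(labels(i)), d);
      if (prev_cost - cost_now < tol) break;
      prev_cost = cost_now;
    }
    prev = labels;

    // median update, restricted to clusters whose membership changed
    std::vector<bool> dirty(k, false);
    for (uword i = 0; i < n; ++i) {
      if (prev_mem(i) != labels(i)) {
        dirty[labels(i)] = true;
        if (prev_mem(i) < k) dirty[prev_mem(i)] = true;
      }
    }
    prev_mem = labels;
    for (uword j = 0; j < k; ++j) members[j].clear();
    for (uword i = 0; i < n; ++i) members[labels(i)].push_back(i);
    double dmax = 0.0;
    delta.zeros();
    for (uword j = 0; j < k; ++j) {
      if (!dirty[j] || members[j].empty()) continue;
      const std::vector<uword>& idx = members[j];
      vec newc(d);
      for (uword t = 0; t < d; ++t) {
        const double* col = X.colptr(t);
        buf.resize(idx.size());
        for (size_t a = 0; a < idx.size(); ++a) buf[a] = col[idx[a]];
        newc(t) = median_inplace(buf);
      }
      delta(j) = l1_dist(newc.memptr(), Ct.colptr(j), d);
      Ct.col(j) = newc;
      if (delta(j) > dmax) dmax = delta(j);
    }
    ++updates;

    // bound-driven reassignment
    for (uword i = 0; i < n; ++i) {
      ub(i) += delta(labels(i));
      lb(i) -= dmax;
      if (ub(i) < lb(i)) continue;
      ub(i) = l1_dist(Xt.colptr(i), Ct.colptr(labels(i)), d);
      if (ub(i) < lb(i)) continue;
      uword a;
      double u, l;
      scan_point(Xt.colptr(i), Ct, a, u, l);
      labels(i) = a;
      ub(i) = u;
      lb(i) = l;
    }
  }

  double cost;
  if (updates == 0 && reseeds == 0) {
    cost = accu(ub);  // bounds are exact straight after a full assignment
  } else {
    cost = 0.0;
    for (uword i = 0; i < n; ++i)
      cost += l1_dist(Xt.colptr(i), Ct.colptr(labels(i)), d);
  }

  return Rcpp::List::create(
      Rcpp::Named("labels") = Rcpp::IntegerVector(labels.begin(), labels.end()),
      Rcpp::Named("centroids") = Ct.t(),
      Rcpp::Named("cost") = cost,
      Rcpp::Named("iterations") = updates,
      Rcpp::Named("reseeds") = reseeds);
}

// [[Rcpp::export]]
arma::mat cpp_pairwise_l1(const arma::mat& X) {
  mat Xt = X.t();
  const uword n = Xt.n_cols, d = Xt.n_rows;
  mat D(n, n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    const double* xi = Xt.colptr(i);
    for (uword j = i + 1; j < n; ++j) {
      double s = l1_dist(xi, Xt.colptr(j), d);
      D(i, j) = s;
      D(j, i) = s;
    }
  }
  return D;
}

// [[Rcpp::export]]
arma::rowvec cpp_colmedians(const arma::mat& X) {
  const uword n = X.n_rows, d = X.n_cols;
  rowvec out(d);
  std::vector<double> buf(n);
  for (uword t = 0; t < d; ++t) {
    const double* col = X.colptr(t);
    buf.assign(col, col + n);
    out(t) = median_inplace(buf);
  }
  return out;
}
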