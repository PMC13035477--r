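#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Row-wise top-k selection on a score matrix. Ties broken by column index so
// results are deterministic regardless of BLAS. Returns 1-based indices.
// [[Rcpp::export(name = ".top_k_rows")]]
IntegerMatrix top_k_rows(NumericMatrix m, int k, bool largest) {
  const int n = m.nrow(), p = m.ncol();
  if (k > p) stop("k exceeds number of columns");
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int> > row(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) {
      double v = m(i, j);
      row[j] = std::make_pair(largest ? -v : v, j);
    }
    std::partial_sort(row.begin(), row.begin() + k, row.end());
    for (int j = 0; j < k; ++j) out(i, j) = row[j].second + 1;
  }
  return out;
}

// k nearest neighbours by Euclidean distance among 2-D (or d-D) points,
// self excluded; ties at the boundary broken by point index.
// [[Rcpp::export(name = ".knn_points")]]
IntegerMatrix knn_points(NumericMatrix x, int k) {
  const int n = x.nrow(), d = x.ncol();
  if (k >= n) stop("k must be smaller than the number of points");
  IntegerMatrix out(n, k);
  std::vector<double> p((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c) p[(size_t)i * d + c] = x(i, c);
  std::vector<std::pair<double, int> > cand(n - 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    const double *pi = &p[(size_t)i * d];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double *pj = &p[(size_t)j * d];
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = pi[c] - pj[c];
        s += diff * diff;
      }
      cand[m++] = std::make_pair(s, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int j = 0; j < k; ++j) out(i, j) = cand[j].second + 1;
  }
  return out;
}

// Exact mean Euclidean distance over all unordered point pairs.
// [[Rcpp::export(name = ".mean_pairwise_dist")]]
double mean_pairwise_dist(NumericMatrix x) {
  const int n = x.nrow(), d = x.ncol();
  if (n < 2) stop("need at least two points");
  // point-major copy so the inner loop is contiguous
  std::vector<double> p((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < d; ++c) p[(size_t)i * d + c] = x(i, c);
  long double total = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    const double *pi = &p[(size_t)i * d];
    for (int j = i + 1; j < n; ++j) {
      const double *pj = &p[(size_t)j * d];
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = pi[c] - pj[c];
        s += diff * diff;
      }
      total += std::sqrt(s);
    }
  }
  long double npairs = (long double)n * (n - 1) / 2.0;
  return (double)(total / npairs);
}

// Neighbour pairs within a radius (strictly positive distances allowed up to
// and including the radius). Returns a two-column matrix of 1-based index
// pairs with i < j.
// [[Rcpp::export(name = ".radius_pairs")]]
IntegerMatrix radius_pairs(NumericMatrix x, double radius) {
  const int n = x.nrow(), d = x.ncol();
  const double r2 = radius * radius;
  std::vector<int> ii, jj;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = x(i, c) - x(j, c);
        s += diff * diff;
      }
      if (s <= r2) { ii.push_back(i + 1); jj.push_back(j + 1); }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) { out(k, 0) = ii[k]; out(k, 1) = jj[k]; }
  return out;
}
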