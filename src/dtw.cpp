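#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Accumulated-cost DTW with the classic three-predecessor step pattern,
// local cost |a - b|, no window. Two-row rolling DP.
static double dtw_core(const double* x, int n, const double* y, int m) {
  std::vector<double> prev(m), cur(m);
  prev[0] = std::fabs(x[0] - y[0]);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + std::fabs(x[0] - y[j]);
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + std::fabs(x[i] - y[0]);
    for (int j = 1; j < m; ++j) {
      double best = std::min(prev[j], std::min(prev[j - 1], cur[j - 1]));
      cur[j] = std::fabs(x[i] - y[j]) + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// [[Rcpp::export(name = ".dtw_distance_cpp")]]
double dtw_distance_cpp(NumericVector x, NumericVector y) {
  if (x.size() < 1 || y.size() < 1)
    stop("sequences must be non-empty");
  return dtw_core(x.begin(), x.size(), y.begin(), y.size());
}

// [[Rcpp::export(name = ".dtw_cost_matrix_cpp")]]
NumericMatrix dtw_cost_matrix_cpp(NumericVector x, NumericVector y) {
  int n = x.size(), m = y.size();
  if (n < 1 || m < 1) stop("sequences must be non-empty");
  NumericMatrix G(n, m);
  G(0, 0) = std::fabs(x[0] - y[0]);
  for (int j = 1; j < m; ++j) G(0, j) = G(0, j - 1) + std::fabs(x[0] - y[j]);
  for (int i = 1; i < n; ++i) {
    G(i, 0) = G(i - 1, 0) + std::fabs(x[i] - y[0]);
    for (int j = 1; j < m; ++j) {
      double best = std::min(G(i - 1, j),
                             std::min(G(i - 1, j - 1), G(i, j - 1)));
      G(i, j) = std::fabs(x[i] - y[j]) + best;
    }
  }
  return G;
}

// Symmetric pairwise DTW over a list of numeric vectors.
// [[Rcpp::export(name = ".dtw_pairwise_cpp")]]
NumericMatrix dtw_pairwise_cpp(List seqs) {
  int n = seqs.size();
  std::vector<NumericVector> v;
  v.reserve(n);
  for (int i = 0; i < n; ++i) v.push_back(as<NumericVector>(seqs[i]));
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = dtw_core(v[i].begin(), v[i].size(),
                          v[j].begin(), v[j].size());
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
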