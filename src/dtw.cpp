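#include <Rcpp.h>
using namespace Rcpp;

// Unconstrained dynamic time warping with |x_i - y_j| local cost.

// [[Rcpp::export]]
double dtw_distance_cpp(NumericVector x, NumericVector y) {
  int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("empty series");
  std::vector<double> prev(m), cur(m);
  prev[0] = std::abs(x[0] - y[0]);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + std::abs(x[0] - y[j]);
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + std::abs(x[i] - y[0]);
    for (int j = 1; j < m; ++j) {
      double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = best + std::abs(x[i] - y[j]);
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// Optimal warping path (1-based indices), backtracked from the full
// cumulative-cost matrix. Returns a 2-column matrix (i, j).

// [[Rcpp::export]]
IntegerMatrix dtw_path_cpp(NumericVector x, NumericVector y) {
  int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("empty series");
  NumericMatrix D(n, m);
  D(0, 0) = std::abs(x[0] - y[0]);
  for (int j = 1; j < m; ++j) D(0, j) = D(0, j - 1) + std::abs(x[0] - y[j]);
  for (int i = 1; i < n; ++i) {
    D(i, 0) = D(i - 1, 0) + std::abs(x[i] - y[0]);
    for (int j = 1; j < m; ++j) {
      double best = std::min(D(i - 1, j),
                             std::min(D(i, j - 1), D(i - 1, j - 1)));
      D(i, j) = best + std::abs(x[i] - y[j]);
    }
  }
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i + 1); pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    if (i == 0) --j;
    else if (j == 0) --i;
    else {
      double d_diag = D(i - 1, j - 1), d_up = D(i - 1, j), d_left = D(i, j - 1);
      if (d_diag <= d_up && d_diag <= d_left) { --i; --j; }
      else if (d_up <= d_left) --i;
      else --j;
    }
    pi.push_back(i + 1); pj.push_back(j + 1);
  }
  int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi[L - 1 - k];
    path(k, 1) = pj[L - 1 - k];
  }
  return path;
}
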