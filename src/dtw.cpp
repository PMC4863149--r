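#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Accumulated-cost DP for scalar series under steps {(1,0),(0,1),(1,1)},
// unit weights, boundary (1,1)..(M,N). Local cost |x_m - y_n|.
// Returns minimal accumulated cost; if path pointers are supplied, also
// backtracks the optimal path, preferring the diagonal step on ties
// (tie rule affects the path and its length K, not the accumulated cost).
static double dtw_core(const double *x, int M, const double *y, int N,
                       int band,
                       std::vector<int> *pi, std::vector<int> *pj) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> D((size_t)M * N, INF);
  for (int m = 0; m < M; ++m) {
    int lo = 0, hi = N - 1;
    if (band >= 0) {
      // Sakoe-Chiba band around the rescaled diagonal
      double c = (N - 1) * (M > 1 ? (double)m / (M - 1) : 0.0);
      lo = std::max(0, (int)std::ceil(c - band));
      hi = std::min(N - 1, (int)std::floor(c + band));
    }
    for (int n = lo; n <= hi; ++n) {
      double d = std::fabs(x[m] - y[n]);
      double best;
      if (m == 0 && n == 0) best = 0.0;
      else {
        best = INF;
        if (m > 0 && n > 0) best = D[(size_t)(m - 1) * N + (n - 1)];
        if (m > 0) best = std::min(best, D[(size_t)(m - 1) * N + n]);
        if (n > 0) best = std::min(best, D[(size_t)m * N + (n - 1)]);
      }
      D[(size_t)m * N + n] = d + best;
    }
  }
  double acc = D[(size_t)(M - 1) * N + (N - 1)];
  if (pi != nullptr) {
    int m = M - 1, n = N - 1;
    pi->push_back(m + 1); pj->push_back(n + 1);
    while (m > 0 || n > 0) {
      double diag = (m > 0 && n > 0) ? D[(size_t)(m - 1) * N + (n - 1)] : INF;
      double up   = (m > 0) ? D[(size_t)(m - 1) * N + n] : INF;
      double left = (n > 0) ? D[(size_t)m * N + (n - 1)] : INF;
      if (diag <= up && diag <= left)      { --m; --n; }
      else if (up <= left)                 { --m; }
      else                                 { --n; }
      pi->push_back(m + 1); pj->push_back(n + 1);
    }
    std::reverse(pi->begin(), pi->end());
    std::reverse(pj->begin(), pj->end());
  }
  return acc;
}

// [[Rcpp::export(name = ".dtw_cpp")]]
List dtw_cpp(NumericVector x, NumericVector y, bool normalize, int band) {
  int M = x.size(), N = y.size();
  std::vector<int> pi, pj;
  double acc = dtw_core(REAL(x), M, REAL(y), N, band, &pi, &pj);
  int K = (int)pi.size();
  double dist = normalize ? acc / K : acc;
  return List::create(_["distance"] = dist, _["accumulated"] = acc,
                      _["K"] = K,
                      _["index_x"] = IntegerVector(pi.begin(), pi.end()),
                      _["index_y"] = IntegerVector(pj.begin(), pj.end()));
}

// [[Rcpp::export(name = ".dtw_pairwise_cpp")]]
NumericMatrix dtw_pairwise_cpp(List trials, bool normalize, int band) {
  int n = trials.size();
  NumericMatrix D(n, n);
  std::vector<NumericVector> tv(n);
  for (int i = 0; i < n; ++i) tv[i] = as<NumericVector>(trials[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      std::vector<int> pi, pj;
      double acc = dtw_core(REAL(tv[i]), tv[i].size(), REAL(tv[j]),
                            tv[j].size(), band,
                            normalize ? &pi : nullptr,
                            normalize ? &pj : nullptr);
      double d = normalize ? acc / pi.size() : acc;
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// [[Rcpp::export(name = ".dtw_cross_cpp")]]
NumericMatrix dtw_cross_cpp(List trials_a, List trials_b, bool normalize,
                            int band) {
  int na = trials_a.size(), nb = trials_b.size();
  NumericMatrix D(na, nb);
  for (int i = 0; i < na; ++i) {
    NumericVector a = trials_a[i];
    for (int j = 0; j < nb; ++j) {
      NumericVector b = trials_b[j];
      std::vector<int> pi, pj;
      double acc = dtw_core(REAL(a), a.size(), REAL(b), b.size(), band,
                            normalize ? &pi : nullptr,
                            normalize ? &pj : nullptr);
      D(i, j) = normalize ? acc / pi.size() : acc;
    }
  }
  return D;
}
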