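#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Sequential minimal optimization for the soft-margin SVM dual on a
// precomputed kernel:
//   min_a 0.5 a'Qa - e'a,  Q_ij = t_i t_j K_ij,  0 <= a_i <= C, t'a = 0,
// with maximal-violating-pair working-set selection. The kernel is used
// as supplied; when the working-set curvature K_ii + K_jj - 2K_ij is not
// positive (possible for indefinite kernels such as Gaussians of DTW
// distances) a small positive surrogate is used, as in LIBSVM.
struct SmoResult { std::vector<double> alpha; double b; int iter; };

static SmoResult smo_solve(const double *K, int n, const double *t,
                           double C, double eps, int max_iter) {
  std::vector<double> a(n, 0.0), G(n, -1.0);
  int it = 0;
  for (; it < max_iter; ++it) {
    // i: max -t_i G_i over I_up; j: min -t_j G_j over I_low
    int i = -1, j = -1;
    double gmax = -std::numeric_limits<double>::infinity();
    double gmin = std::numeric_limits<double>::infinity();
    for (int k = 0; k < n; ++k) {
      bool up  = (t[k] > 0 && a[k] < C) || (t[k] < 0 && a[k] > 0);
      bool low = (t[k] > 0 && a[k] > 0) || (t[k] < 0 && a[k] < C);
      double v = -t[k] * G[k];
      if (up && v > gmax) { gmax = v; i = k; }
      if (low && v < gmin) { gmin = v; j = k; }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) break;

    double Kii = K[(size_t)i * n + i], Kjj = K[(size_t)j * n + j];
    double Kij = K[(size_t)i * n + j];
    // curvature along the working-set direction: d'Qd = Kii + Kjj - 2Kij
    double quad = Kii + Kjj - 2.0 * Kij;
    if (quad <= 0) quad = 1e-12;

    // exact line minimum, clipped to the box with variables snapped
    // exactly onto their bounds (preserves t'a = 0)
    double ai_old = a[i], aj_old = a[j];
    if (t[i] != t[j]) {
      double delta = (-G[i] - G[j]) / quad;
      double diff = a[i] - a[j];
      a[i] += delta; a[j] += delta;
      if (diff > 0) { if (a[j] < 0) { a[j] = 0; a[i] = diff; } }
      else          { if (a[i] < 0) { a[i] = 0; a[j] = -diff; } }
      if (diff > 0) { if (a[i] > C) { a[i] = C; a[j] = C - diff; } }
      else          { if (a[j] > C) { a[j] = C; a[i] = C + diff; } }
    } else {
      double delta = (G[i] - G[j]) / quad;
      double sum = a[i] + a[j];
      a[i] -= delta; a[j] += delta;
      if (sum > C) { if (a[i] > C) { a[i] = C; a[j] = sum - C; } }
      else         { if (a[j] < 0) { a[j] = 0; a[i] = sum; } }
      if (sum > C) { if (a[j] > C) { a[j] = C; a[i] = sum - C; } }
      else         { if (a[i] < 0) { a[i] = 0; a[j] = sum; } }
    }
    double d_i = a[i] - ai_old, d_j = a[j] - aj_old;
    if (std::fabs(d_i) < 1e-15 && std::fabs(d_j) < 1e-15) break;
    for (int k = 0; k < n; ++k)
      G[k] += t[k] * (t[i] * d_i * K[(size_t)i * n + k] +
                      t[j] * d_j * K[(size_t)j * n + k]);
  }
  // offset from free support vectors, else midpoint of the KKT bounds
  double b = 0.0; int nfree = 0;
  double ub = std::numeric_limits<double>::infinity(), lb = -ub;
  for (int k = 0; k < n; ++k) {
    double yg = t[k] * G[k];
    if (a[k] > 1e-10 && a[k] < C - 1e-10) { b += -yg; ++nfree; }
    bool up  = (t[k] > 0 && a[k] < C) || (t[k] < 0 && a[k] > 0);
    bool low = (t[k] > 0 && a[k] > 0) || (t[k] < 0 && a[k] < C);
    if (up)  ub = std::min(ub, -yg);
    if (low) lb = std::max(lb, -yg);
  }
  b = nfree > 0 ? b / nfree : 0.5 * (ub + lb);
  SmoResult r; r.alpha = a; r.b = b; r.iter = it;
  return r;
}

// [[Rcpp::export(name = ".smo_cpp")]]
List smo_cpp(NumericMatrix K, NumericVector t, double C,
             double eps = 1e-6, int max_iter = 100000) {
  int n = K.nrow();
  SmoResult r = smo_solve(REAL(K), n, REAL(t), C, eps, max_iter);
  return List::create(_["alpha"] = NumericVector(r.alpha.begin(), r.alpha.end()),
                      _["b"] = r.b, _["iterations"] = r.iter);
}

// Leave-one-pair-out accuracy over a C grid for one precomputed kernel.
// folds: 1-based fold id per trial; each fold holds one trial per class.
// Decision value for a held-out trial x: sum_i alpha_i t_i K(x, i) + b;
// ties at exactly zero go to +1.
// [[Rcpp::export(name = ".loocv_grid_cpp")]]
NumericVector loocv_grid_cpp(NumericMatrix K, NumericVector t,
                             IntegerVector folds, NumericVector C_grid,
                             double eps = 1e-6) {
  int n = K.nrow(), nc = C_grid.size();
  int nf = 0;
  for (int k = 0; k < n; ++k) nf = std::max(nf, folds[k]);
  NumericVector acc(nc);
  std::vector<int> tr; tr.reserve(n);
  std::vector<double> Ksub((size_t)n * n), tsub(n);
  for (int ci = 0; ci < nc; ++ci) {
    int correct = 0, total = 0;
    for (int f = 1; f <= nf; ++f) {
      tr.clear();
      for (int k = 0; k < n; ++k) if (folds[k] != f) tr.push_back(k);
      int m = (int)tr.size();
      for (int a2 = 0; a2 < m; ++a2) {
        tsub[a2] = t[tr[a2]];
        for (int b2 = 0; b2 < m; ++b2)
          Ksub[(size_t)a2 * m + b2] = K(tr[a2], tr[b2]);
      }
      SmoResult r = smo_solve(Ksub.data(), m, tsub.data(), C_grid[ci],
                              eps, 100000);
      for (int k = 0; k < n; ++k) {
        if (folds[k] != f) continue;
        double dv = r.b;
        for (int a2 = 0; a2 < m; ++a2)
          dv += r.alpha[a2] * tsub[a2] * K(k, tr[a2]);
        double pred = dv >= 0 ? 1.0 : -1.0;
        if (pred == t[k]) ++correct;
        ++total;
      }
    }
    acc[ci] = total > 0 ? (double)correct / total : NA_REAL;
  }
  return acc;
}
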