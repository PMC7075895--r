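#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss linear SVM *without* intercept:
//   min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w.x_i)
// Without a bias term the dual has only box constraints 0 <= alpha_i <= C,
// so plain cyclic coordinate descent converges (Hsieh et al., 2008). The
// intercept-free form preserves the exact origin-symmetry of the
// (A-B) vs (B-A) contrast construction.
//
// X: n x p numeric matrix (row-major access via column pointers),
// y: +1/-1 labels. Returns the weight vector w (length p).
// Stopping: maximum projected-gradient violation over a full sweep below
// `tol` (the standard dual-feasibility criterion, deterministic).
// [[Rcpp::export(name = ".linear_svm_fit")]]
NumericVector linear_svm_fit(NumericMatrix X, NumericVector y, double C,
                             int max_epochs = 200, double tol = 1e-2) {
  int n = X.nrow(), p = X.ncol();
  NumericVector w(p), alpha(n), qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) { double v = X(i, j); s += v * v; }
    qii[i] = s;
  }
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    double max_pg = 0.0;
    for (int i = 0; i < n; ++i) {
      if (qii[i] <= 0.0) continue;
      double dot = 0.0;
      for (int j = 0; j < p; ++j) dot += w[j] * X(i, j);
      double g = y[i] * dot - 1.0;               // gradient of dual coord
      double a_old = alpha[i];
      // projected gradient: zero at an optimal coordinate
      double pg = g;
      if (a_old <= 0.0 && g > 0.0) pg = 0.0;
      else if (a_old >= C && g < 0.0) pg = 0.0;
      double apg = fabs(pg);
      if (apg > max_pg) max_pg = apg;
      double a_new = a_old - g / qii[i];
      if (a_new < 0.0) a_new = 0.0;
      else if (a_new > C) a_new = C;
      double d = a_new - a_old;
      if (d != 0.0) {
        alpha[i] = a_new;
        double dy = d * y[i];
        for (int j = 0; j < p; ++j) w[j] += dy * X(i, j);
      }
    }
    if (max_pg < tol) break;
  }
  return w;
}
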