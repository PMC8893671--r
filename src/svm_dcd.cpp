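#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) linear SVM:
//   min_w 0.5*||w||^2 + C * sum_i max(0, 1 - y_i * w.x_i)
// with the bias absorbed as an augmented constant feature. Deterministic
// cyclic sweeps (no random permutation) so refits are bit-reproducible.
// [[Rcpp::export(name = ".svm_dcd")]]
List svm_dcd(NumericMatrix X, NumericVector y, double C,
             double tol = 1e-10, int max_pass = 5000) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> w(p, 0.0), alpha(n, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  int pass = 0;
  bool converged = false;
  for (pass = 0; pass < max_pass; ++pass) {
    double max_pg = 0.0;
    for (int i = 0; i < n; ++i) {
      if (qii[i] <= 0.0) continue;
      double wx = 0.0;
      for (int j = 0; j < p; ++j) wx += w[j] * X(i, j);
      double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > max_pg) max_pg = std::fabs(PG);
      if (std::fabs(PG) > 1e-14) {
        double a_new = alpha[i] - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        double d = (a_new - alpha[i]) * y[i];
        if (d != 0.0) {
          for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
          alpha[i] = a_new;
        }
      }
    }
    if (max_pg < tol) { converged = true; break; }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["passes"] = pass + 1, _["converged"] = converged);
}
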