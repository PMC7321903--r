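// Cyclic coordinate descent for non-negative least squares on the
// normal equations: min ||Ax - y||, x >= 0, given AtA and Aty. Exact
// zeros by projection; deterministic sweep order; stops when the KKT
// violation falls below `tol` or after `max_sweeps`.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector nnls_cd_cpp(NumericMatrix AtA, NumericVector Aty,
                          int max_sweeps, double tol) {
  int p = Aty.size();
  NumericVector x(p);
  std::vector<double> r(Aty.begin(), Aty.end());  // r = Aty - AtA x
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double kkt = 0.0;
    for (int j = 0; j < p; ++j) {
      double ajj = AtA(j, j);
      if (ajj <= 0) continue;
      double xj_new = x[j] + r[j] / ajj;
      if (xj_new < 0) xj_new = 0;
      double delta = xj_new - x[j];
      if (delta != 0.0) {
        const double* col = &AtA(0, j);
        for (int i = 0; i < p; ++i) r[i] -= col[i] * delta;
        x[j] = xj_new;
      }
      double viol = (x[j] > 0) ? std::fabs(r[j]) : (r[j] > 0 ? r[j] : 0.0);
      if (viol > kkt) kkt = viol;
    }
    if (kkt <= tol) break;
  }
  return x;
}
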