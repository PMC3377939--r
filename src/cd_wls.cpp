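#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cyclic coordinate descent for the penalized weighted least-squares problem
//   minimize 0.5 * sum_i w_i (z_i - sum_j x_ij theta_j)^2
//            + lambda * sum_{j penalized} |theta_j|
// which is the inner problem of the quadratic approximation to the L1-
// penalized Cox log partial likelihood.  Unpenalized coordinates (the
// mandatory clinical covariates) get plain Gauss-Seidel updates.
// [[Rcpp::export(name = ".cd_wls")]]
NumericVector cd_wls(NumericMatrix X, NumericVector w, NumericVector z,
                     double lambda, LogicalVector penalized,
                     NumericVector theta0, double tol, int maxit) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector theta = clone(theta0);
  std::vector<double> r(n), xwx(p);

  for (int i = 0; i < n; i++) {
    double s = 0.0;
    for (int j = 0; j < p; j++) s += X(i, j) * theta[j];
    r[i] = z[i] - s;
  }
  for (int j = 0; j < p; j++) {
    double s = 0.0;
    for (int i = 0; i < n; i++) s += w[i] * X(i, j) * X(i, j);
    xwx[j] = s;
  }

  for (int it = 0; it < maxit; it++) {
    double maxdel = 0.0;
    for (int j = 0; j < p; j++) {
      if (xwx[j] <= 0.0) continue;
      double num = 0.0;
      for (int i = 0; i < n; i++) num += w[i] * X(i, j) * r[i];
      num += xwx[j] * theta[j];
      double tj;
      if (penalized[j]) {
        double a = std::fabs(num) - lambda;
        tj = (a <= 0.0) ? 0.0 : ((num > 0.0 ? a : -a) / xwx[j]);
      } else {
        tj = num / xwx[j];
      }
      double d = tj - theta[j];
      if (d != 0.0) {
        for (int i = 0; i < n; i++) r[i] -= d * X(i, j);
        theta[j] = tj;
        double ad = std::fabs(d);
        if (ad > maxdel) maxdel = ad;
      }
    }
    if (maxdel < tol) break;
  }
  return theta;
}
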