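#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for one SLIM column:
//   min_w 1/2 w'Gw - c'w + beta/2 ||w||^2 + lambda ||w||_1
//   s.t.  w >= 0, w[exclude] = 0
// where G = X'X is the participants' Gram matrix and c = X'y the covariance
// of the target column with its peers. The closed-form coordinate update is
//   w_j <- max(0, (c_j - sum_{k != j} G_jk w_k - lambda) / (G_jj + beta)).
// q = G w is maintained incrementally so each update costs O(n).
// [[Rcpp::export]]
List slim_cd_col(const NumericMatrix& G, const NumericVector& c, int exclude,
                 double beta, double lambda, int max_iter, double tol) {
  const int n = G.ncol();
  NumericVector w(n), q(n);
  double maxdelta = 0.0;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    maxdelta = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == exclude) continue;
      const double denom = G(j, j) + beta;
      if (denom <= 0.0) continue;
      const double num = c[j] - (q[j] - G(j, j) * w[j]) - lambda;
      const double wj = num > 0.0 ? num / denom : 0.0;
      const double d = wj - w[j];
      if (d != 0.0) {
        for (int k = 0; k < n; ++k) q[k] += d * G(k, j);
        w[j] = wj;
        const double ad = d < 0.0 ? -d : d;
        if (ad > maxdelta) maxdelta = ad;
      }
    }
    if (maxdelta <= tol) break;
  }
  return List::create(_["w"] = w,
                      _["iterations"] = it + 1,
                      _["converged"] = maxdelta <= tol,
                      _["last_delta"] = maxdelta);
}
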