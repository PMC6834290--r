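#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// One full EM run for a 1-D Gaussian mixture from the given initialization.
// Returns R_NilValue when a component collapses (vanishing weight or
// variance) or the log-likelihood becomes non-finite, so the caller can
// treat the restart as failed.
// [[Rcpp::export]]
SEXP em_gmm_1d_cpp(NumericVector x, NumericVector means0, NumericVector sds0,
                   NumericVector w0, int max_iter, double tol) {
  const int n = x.size(), k = means0.size();
  if (k > 8) stop("at most 8 mixture components are supported");
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> mu(means0.begin(), means0.end());
  std::vector<double> sd(sds0.begin(), sds0.end());
  std::vector<double> r(static_cast<size_t>(n) * k);
  const double log2pi = std::log(2.0 * M_PI);
  double ll = R_NegInf;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    // E step
    double ll_new = 0.0;
    std::vector<double> lw(k), lsd(k), inv2v(k);
    for (int j = 0; j < k; ++j) {
      lw[j] = std::log(w[j]);
      lsd[j] = std::log(sd[j]);
      inv2v[j] = 0.5 / (sd[j] * sd[j]);
    }
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      double ld[8];
      for (int j = 0; j < k; ++j) {
        double d = x[i] - mu[j];
        ld[j] = lw[j] - lsd[j] - 0.5 * log2pi - d * d * inv2v[j];
        if (ld[j] > mx) mx = ld[j];
      }
      double s = 0.0;
      for (int j = 0; j < k; ++j) s += std::exp(ld[j] - mx);
      double lse = mx + std::log(s);
      ll_new += lse;
      for (int j = 0; j < k; ++j) r[static_cast<size_t>(i) * k + j] = std::exp(ld[j] - lse);
    }
    if (!std::isfinite(ll_new)) return R_NilValue;
    // M step
    for (int j = 0; j < k; ++j) {
      double nk = 0.0, sx = 0.0;
      for (int i = 0; i < n; ++i) {
        double rij = r[static_cast<size_t>(i) * k + j];
        nk += rij; sx += rij * x[i];
      }
      if (nk < 1e-8) return R_NilValue;
      double m = sx / nk, sv = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = x[i] - m;
        sv += r[static_cast<size_t>(i) * k + j] * d * d;
      }
      double v = sv / nk;
      if (v < 1e-10) return R_NilValue;
      w[j] = nk / n; mu[j] = m; sd[j] = std::sqrt(v);
    }
    bool converged = std::fabs(ll_new - ll) < tol * (1.0 + std::fabs(ll_new));
    ll = ll_new;
    if (converged) break;
  }
  return List::create(_["weights"] = wrap(w), _["means"] = wrap(mu),
                      _["sds"] = wrap(sd), _["loglik"] = ll,
                      _["iterations"] = std::min(it, max_iter));
}
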