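#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Batch-normalization kernels over (rows = positions*samples, cols =
// channels) feature matrices.

// [[Rcpp::export(rng = false)]]
List bn_train_cpp(NumericMatrix x, NumericVector gamma, NumericVector beta,
                  double eps) {
  const R_xlen_t m = x.nrow();
  const int C = x.ncol();
  NumericMatrix y(m, C), xhat(m, C);
  NumericVector mu(C), va(C), inv_sd(C);
  for (int j = 0; j < C; ++j) {
    const double *xc = &x(0, j);
    double s = 0.0, s2 = 0.0;
    for (R_xlen_t i = 0; i < m; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    const double mean = s / m;
    double var = s2 / m - mean * mean;
    if (var < 0) var = 0;
    const double isd = 1.0 / std::sqrt(var + eps);
    mu[j] = mean; va[j] = var; inv_sd[j] = isd;
    const double g = gamma[j], b = beta[j];
    double *yc = &y(0, j), *hc = &xhat(0, j);
    for (R_xlen_t i = 0; i < m; ++i) {
      const double h = (xc[i] - mean) * isd;
      hc[i] = h;
      yc[i] = g * h + b;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mean"] = mu,
                      _["var"] = va, _["inv_sd"] = inv_sd);
}

// [[Rcpp::export(rng = false)]]
NumericMatrix bn_infer_cpp(NumericMatrix x, NumericVector gamma,
                           NumericVector beta, NumericVector mean,
                           NumericVector var, double eps) {
  const R_xlen_t m = x.nrow();
  const int C = x.ncol();
  NumericMatrix y(m, C);
  for (int j = 0; j < C; ++j) {
    const double isd = 1.0 / std::sqrt(var[j] + eps);
    const double g = gamma[j], b = beta[j], mu = mean[j];
    const double *xc = &x(0, j);
    double *yc = &y(0, j);
    for (R_xlen_t i = 0; i < m; ++i) yc[i] = g * (xc[i] - mu) * isd + b;
  }
  return y;
}

// Gradient through training-mode batch normalization (batch statistics
// participate in the gradient).  Overwrites nothing; returns dx, dgamma,
// dbeta.
// [[Rcpp::export(rng = false)]]
List bn_bwd_cpp(NumericMatrix g, NumericMatrix xhat, NumericVector gamma,
                NumericVector inv_sd) {
  const R_xlen_t m = g.nrow();
  const int C = g.ncol();
  NumericMatrix dx(m, C);
  NumericVector dgamma(C), dbeta(C);
  for (int j = 0; j < C; ++j) {
    const double *gc = &g(0, j), *hc = &xhat(0, j);
    double sg = 0.0, sgh = 0.0;
    for (R_xlen_t i = 0; i < m; ++i) { sg += gc[i]; sgh += gc[i] * hc[i]; }
    dgamma[j] = sgh; dbeta[j] = sg;
    const double gam = gamma[j], isd = inv_sd[j];
    const double mean_d = gam * sg / m, mean_dh = gam * sgh / m;
    double *dc = &dx(0, j);
    for (R_xlen_t i = 0; i < m; ++i)
      dc[i] = (gam * gc[i] - mean_d - hc[i] * mean_dh) * isd;
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
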