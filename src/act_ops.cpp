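#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Elementwise activation kernels.  Codes follow list_activations() order:
// 1 relu, 2 leaky_relu, 3 clipped_relu, 4 elu, 5 gelu, 6 tanh,
// 7 softsign, 8 swish, 9 rectified_softsign.

static inline double sigmoid(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// [[Rcpp::export(rng = false)]]
NumericVector act_fwd_cpp(int code, NumericVector x, double slope,
                          double ceiling, double alpha, double c0) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  const double *xp = x.begin();
  double *op = out.begin();
  switch (code) {
  case 1: for (R_xlen_t i = 0; i < n; ++i) op[i] = xp[i] > 0 ? xp[i] : 0.0;
    break;
  case 2: for (R_xlen_t i = 0; i < n; ++i)
      op[i] = xp[i] < 0 ? slope * xp[i] : xp[i];
    break;
  case 3: for (R_xlen_t i = 0; i < n; ++i) {
      double v = xp[i] < 0 ? 0.0 : xp[i];
      op[i] = v > ceiling ? ceiling : v;
    }
    break;
  case 4: for (R_xlen_t i = 0; i < n; ++i)
      op[i] = xp[i] < 0 ? alpha * (std::exp(xp[i]) - 1.0) : xp[i];
    break;
  case 5: for (R_xlen_t i = 0; i < n; ++i)
      op[i] = 0.5 * xp[i] * (1.0 + std::erf(c0 * xp[i]));
    break;
  case 6: for (R_xlen_t i = 0; i < n; ++i) op[i] = std::tanh(xp[i]);
    break;
  case 7: for (R_xlen_t i = 0; i < n; ++i)
      op[i] = xp[i] / (1.0 + std::fabs(xp[i]));
    break;
  case 8: for (R_xlen_t i = 0; i < n; ++i) op[i] = xp[i] * sigmoid(xp[i]);
    break;
  case 9: for (R_xlen_t i = 0; i < n; ++i)
      op[i] = xp[i] < 0 ? 0.0 : xp[i] / (1.0 + xp[i]);
    break;
  default: stop("unknown activation code");
  }
  return out;
}

// Derivatives; at the kinks the right-hand limit applies (see the R docs).
// [[Rcpp::export(rng = false)]]
NumericVector act_bwd_cpp(int code, NumericVector x, double slope,
                          double ceiling, double alpha, double c0) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  const double *xp = x.begin();
  double *op = out.begin();
  const double inv_sqrt_pi = 0.5641895835477563;
  switch (code) {
  case 1: for (R_xlen_t i = 0; i < n; ++i) op[i] = xp[i] >= 0 ? 1.0 : 0.0;
    break;
  case 2: for (R_xlen_t i = 0; i < n; ++i) op[i] = xp[i] < 0 ? slope : 1.0;
    break;
  case 3: for (R_xlen_t i = 0; i < n; ++i)
      op[i] = (xp[i] >= 0 && xp[i] < ceiling) ? 1.0 : 0.0;
    break;
  case 4: for (R_xlen_t i = 0; i < n; ++i)
      op[i] = xp[i] < 0 ? alpha * std::exp(xp[i]) : 1.0;
    break;
  case 5: for (R_xlen_t i = 0; i < n; ++i) {
      double z = c0 * xp[i];
      op[i] = 0.5 * (1.0 + std::erf(z)) +
        xp[i] * c0 * inv_sqrt_pi * std::exp(-z * z);
    }
    break;
  case 6: for (R_xlen_t i = 0; i < n; ++i) {
      double t = std::tanh(xp[i]);
      op[i] = 1.0 - t * t;
    }
    break;
  case 7: for (R_xlen_t i = 0; i < n; ++i) {
      double d = 1.0 + std::fabs(xp[i]);
      op[i] = 1.0 / (d * d);
    }
    break;
  case 8: for (R_xlen_t i = 0; i < n; ++i) {
      double s = sigmoid(xp[i]);
      op[i] = s + xp[i] * s * (1.0 - s);
    }
    break;
  case 9: for (R_xlen_t i = 0; i < n; ++i) {
      if (xp[i] < 0) { op[i] = 0.0; }
      else { double d = 1.0 + xp[i]; op[i] = 1.0 / (d * d); }
    }
    break;
  default: stop("unknown activation code");
  }
  return out;
}

// Fused backward for the training hot path: g * F'(x) with one output
// allocation.
// [[Rcpp::export(rng = false)]]
NumericVector act_bwd_mul_cpp(int code, NumericVector x, NumericVector g,
                              double slope, double ceiling, double alpha,
                              double c0) {
  NumericVector d = act_bwd_cpp(code, x, slope, ceiling, alpha, c0);
  const double *gp = g.begin();
  double *dp = d.begin();
  const R_xlen_t n = d.size();
  for (R_xlen_t i = 0; i < n; ++i) dp[i] *= gp[i];
  return d;
}
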