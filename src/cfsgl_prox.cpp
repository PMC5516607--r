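#include <Rcpp.h>
using namespace Rcpp;

// Exact 1-D total-variation proximal operator (fused-lasso signal
// approximator without the L1 term): minimizes
//   0.5 * sum_k (x_k - y_k)^2 + lam * sum_k |x_{k+1} - x_k|
// by Condat's direct non-iterative algorithm (running lower/upper taut
// strings with jump detection). O(N) in practice, exact up to rounding.
static void tv1d_condat(const double *y, double *x, const int n,
                        const double lam) {
  if (n == 1) { x[0] = y[0]; return; }
  if (lam <= 0.0) { for (int i = 0; i < n; ++i) x[i] = y[i]; return; }

  int k = 0, k0 = 0, km = 0, kp = 0; /* current, segment start, last -/+ */
  double vmin = y[0] - lam, vmax = y[0] + lam;
  double umin = lam, umax = -lam;

  for (;;) {
    while (k < n - 1) {
      if (y[k + 1] + umin < vmin - lam) { /* negative jump */
        for (int i = k0; i <= km; ++i) x[i] = vmin;
        k = k0 = km = kp = km + 1;
        vmin = y[k]; vmax = y[k] + 2.0 * lam;
        umin = lam; umax = -lam;
      } else if (y[k + 1] + umax > vmax + lam) { /* positive jump */
        for (int i = k0; i <= kp; ++i) x[i] = vmax;
        k = k0 = km = kp = kp + 1;
        vmin = y[k] - 2.0 * lam; vmax = y[k];
        umin = lam; umax = -lam;
      } else { /* no jump: extend segment */
        ++k;
        umin += y[k] - vmin;
        umax += y[k] - vmax;
        if (umin >= lam) {
          vmin += (umin - lam) / (k - k0 + 1);
          umin = lam;
          km = k;
        }
        if (umax <= -lam) {
          vmax += (umax + lam) / (k - k0 + 1);
          umax = -lam;
          kp = k;
        }
      }
    }
    /* boundary handling at the last sample */
    if (umin < 0.0) { /* negative jump at the end */
      for (int i = k0; i <= km; ++i) x[i] = vmin;
      k = k0 = km = km + 1;
      vmin = y[k];
      umin = lam;
      umax = y[k] + lam - vmax;
      if (k == n - 1) { x[k] = vmin + umin; return; }
    } else if (umax > 0.0) { /* positive jump at the end */
      for (int i = k0; i <= kp; ++i) x[i] = vmax;
      k = k0 = kp = kp + 1;
      vmax = y[k];
      umax = -lam;
      umin = y[k] - lam - vmin;
      if (k == n - 1) { x[k] = vmax + umax; return; }
    } else { /* taut string ends inside the tube */
      const double v = vmin + umin / (k - k0 + 1);
      for (int i = k0; i <= n - 1; ++i) x[i] = v;
      return;
    }
  }
}

static inline double soft(const double v, const double t) {
  if (v > t) return v - t;
  if (v < -t) return v + t;
  return 0.0;
}

// [[Rcpp::export(name = ".tv1d")]]
NumericVector tv1d_cpp(NumericVector y, double lam) {
  const int n = y.size();
  NumericVector x(n);
  tv1d_condat(y.begin(), x.begin(), n, lam);
  return x;
}

// Row-wise fused sparse group lasso proximal operator. For each row v of V:
//   u  = soft-threshold( TV-prox(v, l2), l1 )        (exact FLSA)
//   row <- max(0, 1 - l3 / ||u||_2) * u              (group shrinkage)
// The lambdas passed here are already multiplied by the gradient step.
// [[Rcpp::export(name = ".prox_fsgl_rows")]]
NumericMatrix prox_fsgl_rows_cpp(NumericMatrix V, double l1, double l2,
                                 double l3) {
  const int d = V.nrow(), t = V.ncol();
  NumericMatrix W(d, t);
  std::vector<double> v(t), u(t);
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j < t; ++j) v[j] = V(i, j);
    tv1d_condat(v.data(), u.data(), t, l2);
    double nrm2 = 0.0;
    for (int j = 0; j < t; ++j) {
      u[j] = soft(u[j], l1);
      nrm2 += u[j] * u[j];
    }
    double scale = 0.0;
    if (nrm2 > 0.0) {
      const double nrm = std::sqrt(nrm2);
      scale = (nrm > l3) ? (1.0 - l3 / nrm) : 0.0;
    }
    for (int j = 0; j < t; ++j) W(i, j) = scale * u[j];
  }
  return W;
}
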