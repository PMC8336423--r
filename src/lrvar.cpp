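#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Bartlett-tapered long-run variance of a (mean-centered) buffer:
//   delta * (g0 + 2 * sum_{s=1..w} (1 - s/(w+1)) * gs),
// gs = (1/n) sum_t y_t y_{t+s}.  The 1/n normalization keeps the kernel
// estimate positive semidefinite.
static double lrv_buffer(const std::vector<double> &y, int window, double delta) {
  const int n = (int)y.size();
  double lrv = 0.0;
  for (int s = 0; s <= window; ++s) {
    const int m = n - s;
    const double *a = y.data(), *b = y.data() + s;
    // multiple accumulators break the floating-point latency chain
    double a0 = 0.0, a1 = 0.0, a2 = 0.0, a3 = 0.0,
           a4 = 0.0, a5 = 0.0, a6 = 0.0, a7 = 0.0;
    int i = 0;
    for (; i + 7 < m; i += 8) {
      a0 += a[i] * b[i];         a1 += a[i + 1] * b[i + 1];
      a2 += a[i + 2] * b[i + 2]; a3 += a[i + 3] * b[i + 3];
      a4 += a[i + 4] * b[i + 4]; a5 += a[i + 5] * b[i + 5];
      a6 += a[i + 6] * b[i + 6]; a7 += a[i + 7] * b[i + 7];
    }
    for (; i < m; ++i) a0 += a[i] * b[i];
    const double g = (((a0 + a1) + (a2 + a3)) + ((a4 + a5) + (a6 + a7))) / n;
    lrv += (s == 0) ? g : 2.0 * (1.0 - (double)s / (window + 1.0)) * g;
  }
  return delta * std::max(lrv, 0.0);
}

// [[Rcpp::export]]
NumericVector lrvar_bartlett_cpp(NumericMatrix x, int window, double delta) {
  const int n = x.nrow(), p = x.ncol();
  if (window < 0) stop("window must be nonnegative");
  if (window >= n) stop("window must be smaller than the series length");
  NumericVector out(p);
  std::vector<double> y(n);
  for (int j = 0; j < p; ++j) {
    long double mean = 0.0;
    for (int i = 0; i < n; ++i) mean += x(i, j);
    mean /= n;
    for (int i = 0; i < n; ++i) y[i] = x(i, j) - (double)mean;
    out[j] = lrv_buffer(y, window, delta);
  }
  return out;
}

// Long-run variance of the first-order loss series
//   F_lm(x_t, y_t) = (g_l(x) g_m(y) + g_l(y) g_m(x)) / 2
//                    - lam_m (g_l(x) g_m(x) + g_l(y) g_m(y)) / 2
// along a trajectory, where x_t = frame t, y_t = frame t + kf of the
// eigenfunction value matrix G.  One series per (l, m) pair (1-based
// indices); building the series in place avoids large R temporaries.
// [[Rcpp::export]]
NumericVector pair_lrvar_cpp(NumericMatrix G, int kf, NumericVector lambda,
                             IntegerVector lidx, IntegerVector midx,
                             int window, double delta) {
  const int N = G.nrow();
  const int np = N - kf;
  const int P = lidx.size();
  if (np <= window) stop("window must be smaller than the lagged series length");
  NumericVector out(P);
  std::vector<double> y(np);
  for (int p = 0; p < P; ++p) {
    const int l = lidx[p] - 1, m = midx[p] - 1;
    if (l < 0 || l >= G.ncol() || m < 0 || m >= G.ncol())
      stop("pair index out of range");
    const double lam = lambda[m];
    const double *gl = &G(0, l), *gm = &G(0, m);
    long double mean = 0.0;
    for (int t = 0; t < np; ++t) {
      const double xl = gl[t], yl = gl[t + kf];
      const double xm = gm[t], ym = gm[t + kf];
      const double f = 0.5 * (xl * ym + yl * xm) - 0.5 * lam * (xl * xm + yl * ym);
      y[t] = f;
      mean += f;
    }
    mean /= np;
    for (int t = 0; t < np; ++t) y[t] -= (double)mean;
    out[p] = lrv_buffer(y, window, delta);
  }
  return out;
}
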