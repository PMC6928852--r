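#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Strict local extrema of a sequence; a plateau (run of equal values) that is
// higher/lower than both neighbours is reported once at its midpoint index.
// Endpoints are never extrema. Indices are 1-based for the R side.
static void extrema_scan(const NumericVector& x,
                         std::vector<int>& maxima,
                         std::vector<int>& minima) {
  const int n = x.size();
  int last_sign = 0;  // sign of the previous nonzero first difference
  int last_i = -1;    // position of that difference (between last_i, last_i+1)
  for (int i = 0; i < n - 1; ++i) {
    double d = x[i + 1] - x[i];
    int s = (d > 0.0) - (d < 0.0);
    if (s == 0) continue;
    if (last_sign != 0 && s != last_sign) {
      int idx = (last_i + 1 + i) / 2;  // plateau midpoint (0-based)
      if (last_sign > 0) maxima.push_back(idx + 1);
      else               minima.push_back(idx + 1);
    }
    last_sign = s;
    last_i = i;
  }
}

// [[Rcpp::export]]
List find_extrema_cpp(NumericVector x) {
  if (x.size() < 3) stop("need at least 3 samples to locate extrema");
  std::vector<int> mx, mn;
  extrema_scan(x, mx, mn);
  return List::create(_["maxima"] = wrap(mx), _["minima"] = wrap(mn));
}

// Natural cubic spline through (t, y), t strictly increasing, evaluated at
// query positions 1..n. Queries outside [t_first, t_last] use the end cubic.
static void natural_spline_eval(const std::vector<double>& t,
                                const std::vector<double>& y,
                                int n, std::vector<double>& out) {
  const int m = (int)t.size();
  out.assign(n, 0.0);
  if (m == 1) {
    for (int q = 0; q < n; ++q) out[q] = y[0];
    return;
  }
  if (m == 2) {
    double slope = (y[1] - y[0]) / (t[1] - t[0]);
    for (int q = 0; q < n; ++q) out[q] = y[0] + slope * ((q + 1) - t[0]);
    return;
  }
  // second derivatives M with natural boundary conditions, Thomas algorithm
  std::vector<double> h(m - 1), a(m, 0.0), b(m, 0.0), c(m, 0.0), d(m, 0.0), M(m, 0.0);
  for (int i = 0; i < m - 1; ++i) h[i] = t[i + 1] - t[i];
  b[0] = 1.0; b[m - 1] = 1.0;
  for (int i = 1; i < m - 1; ++i) {
    a[i] = h[i - 1];
    b[i] = 2.0 * (h[i - 1] + h[i]);
    c[i] = h[i];
    d[i] = 6.0 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]);
  }
  std::vector<double> cp(m, 0.0), dp(m, 0.0);
  cp[0] = c[0] / b[0];
  dp[0] = d[0] / b[0];
  for (int i = 1; i < m; ++i) {
    double denom = b[i] - a[i] * cp[i - 1];
    cp[i] = (i < m - 1) ? c[i] / denom : 0.0;
    dp[i] = (d[i] - a[i] * dp[i - 1]) / denom;
  }
  M[m - 1] = dp[m - 1];
  for (int i = m - 2; i >= 0; --i) M[i] = dp[i] - cp[i] * M[i + 1];

  int seg = 0;
  for (int q = 0; q < n; ++q) {
    double p = q + 1;
    while (seg < m - 2 && p > t[seg + 1]) ++seg;
    double hi = h[seg];
    double A = (t[seg + 1] - p) / hi;
    double B = (p - t[seg]) / hi;
    out[q] = A * y[seg] + B * y[seg + 1] +
      ((A * A * A - A) * M[seg] + (B * B * B - B) * M[seg + 1]) * hi * hi / 6.0;
  }
}

// Mirror-extend up to two extrema beyond each end so the envelope covers the
// whole support, the standard remedy for spline end swings in EMD.
static void mirrored_knots(const std::vector<int>& idx, const NumericVector& x,
                           int n, std::vector<double>& t, std::vector<double>& y) {
  const int m = (int)idx.size();
  const int k = std::min(2, m);
  t.clear(); y.clear();
  for (int j = k - 1; j >= 0; --j) {  // left mirror about sample 1
    t.push_back(2.0 - (double)idx[j]);
    y.push_back(x[idx[j] - 1]);
  }
  for (int j = 0; j < m; ++j) {
    t.push_back((double)idx[j]);
    y.push_back(x[idx[j] - 1]);
  }
  for (int j = m - 1; j >= m - k; --j) {  // right mirror about sample n
    t.push_back(2.0 * n - (double)idx[j]);
    y.push_back(x[idx[j] - 1]);
  }
}

// Mean of upper and lower spline envelopes; the trend fallback (fewer than
// two maxima or two minima) returns the input itself.
static NumericVector local_mean_impl(const NumericVector& x) {
  const int n = x.size();
  std::vector<int> mx, mn;
  extrema_scan(x, mx, mn);
  if ((int)mx.size() < 2 || (int)mn.size() < 2) return clone(x);
  std::vector<double> t, y, up, lo;
  mirrored_knots(mx, x, n, t, y);
  natural_spline_eval(t, y, n, up);
  mirrored_knots(mn, x, n, t, y);
  natural_spline_eval(t, y, n, lo);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = 0.5 * (up[i] + lo[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector local_mean_cpp(NumericVector x) {
  if (x.size() < 3) stop("need at least 3 samples for a local mean");
  return local_mean_impl(x);
}

// Classic EMD: repeated sifting with the Cauchy SD stopping criterion.
// Returns the modes as columns of a matrix plus the final residue; the
// telescoping construction makes modes + residue reproduce the input.
// [[Rcpp::export]]
List emd_cpp(NumericVector x, double sd_threshold, int max_sift, int max_modes) {
  const int n = x.size();
  if (n < 8) stop("input too short for decomposition (need >= 8 samples)");
  NumericVector r = clone(x);
  std::vector<NumericVector> modes;
  double amp0 = 0.0;
  for (int i = 0; i < n; ++i) amp0 = std::max(amp0, std::fabs(x[i]));

  for (int l = 0; l < max_modes; ++l) {
    std::vector<int> mx, mn;
    extrema_scan(r, mx, mn);
    // envelopes need two maxima and two minima; otherwise r is a trend
    if ((int)mx.size() < 2 || (int)mn.size() < 2) break;
    double amp = 0.0;
    for (int i = 0; i < n; ++i) amp = std::max(amp, std::fabs(r[i]));
    if (amp <= 1e-12 * amp0) break;               // residue numerically zero

    NumericVector h = clone(r);
    for (int it = 0; it < max_sift; ++it) {
      std::vector<int> hx, hn;
      extrema_scan(h, hx, hn);
      if ((int)hx.size() < 2 || (int)hn.size() < 2) break;  // envelope lost
      NumericVector m = local_mean_impl(h);
      // Huang's sifting SD: sum over samples of the pointwise squared
      // relative change between consecutive sift iterates
      double sd = 0.0, den_all = 0.0;
      for (int i = 0; i < n; ++i) {
        double hi2 = h[i] * h[i];
        den_all += hi2;
        if (hi2 > 0.0) sd += (m[i] * m[i]) / hi2;
      }
      if (den_all <= 0.0) break;
      for (int i = 0; i < n; ++i) h[i] -= m[i];
      if (sd < sd_threshold) break;
    }
    modes.push_back(h);
    for (int i = 0; i < n; ++i) r[i] -= h[i];
  }

  const int L = (int)modes.size();
  NumericMatrix mm(n, std::max(L, 1));
  if (L == 0) {
    std::fill(mm.begin(), mm.end(), 0.0);
  } else {
    for (int l = 0; l < L; ++l)
      std::copy(modes[l].begin(), modes[l].end(), mm.column(l).begin());
  }
  return List::create(_["modes"] = mm, _["residue"] = r, _["n_modes"] = L);
}
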