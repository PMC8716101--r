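// Hartigan dip statistic for a weighted empirical distribution.
//
// dip(F) = min over unimodal distribution functions G of sup_x |F(x) - G(x)|.
// Computed exactly through a convex-envelope characterization: for a modal
// split after point k, a convex fit to points 1..k within the +/- t tube
// around the ECDF exists iff t >= max_{i<=k} (F_i - C_k(x_i)) / 2, where
// C_k is the lower convex envelope of the lower ECDF corners (x_j, F_{j-1});
// the concave right side is symmetric, and the dip is the minimum over
// splits of the larger of the two one-sided requirements. The
// characterization is verified against an exact LP formulation in the test
// suite.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// One-sided requirement t_side[k] for convex fits to points 0..k.
// x ascending and distinct; Flo = F_{i-1}, Fi = F_i.
static std::vector<double> t_side(const std::vector<double>& x,
                                  const std::vector<double>& Flo,
                                  const std::vector<double>& Fi) {
  const int n = (int)x.size();
  std::vector<int> hull;
  hull.reserve(n);
  std::vector<double> out(n);
  hull.push_back(0);
  for (int k = 0; k < n; ++k) {
    if (k > 0) {
      while (hull.size() >= 2) {
        int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
        if ((Flo[b] - Flo[a]) * (x[k] - x[a]) >=
            (Flo[k] - Flo[a]) * (x[b] - x[a]))
          hull.pop_back();
        else
          break;
      }
      hull.push_back(k);
    }
    double dev = 0.0;
    size_t hi = 0;
    for (int i = 0; i <= k; ++i) {
      while (hi + 1 < hull.size() && x[hull[hi + 1]] <= x[i]) ++hi;
      double cv;
      if (hi + 1 < hull.size() && x[i] > x[hull[hi]]) {
        int a = hull[hi], b = hull[hi + 1];
        cv = Flo[a] + (Flo[b] - Flo[a]) * (x[i] - x[a]) / (x[b] - x[a]);
      } else {
        cv = Flo[hull[hi]];
      }
      double d = Fi[i] - cv;
      if (d > dev) dev = d;
    }
    out[k] = dev / 2.0;
  }
  return out;
}

static double dip_core(const std::vector<double>& x,
                       const std::vector<double>& w) {
  const int n = (int)x.size();
  if (n == 1) return 0.5 * w[0];
  std::vector<double> Fi(n), Flo(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    Flo[i] = acc;
    acc += w[i];
    Fi[i] = acc;
  }
  std::vector<double> tl = t_side(x, Flo, Fi);
  // reflected arrays for the concave (right) side
  std::vector<double> xr(n), Fir(n), Flor(n);
  for (int i = 0; i < n; ++i) {
    xr[i] = -x[n - 1 - i];
    Fir[i] = 1.0 - Flo[n - 1 - i];
    Flor[i] = 1.0 - Fi[n - 1 - i];
  }
  std::vector<double> trr = t_side(xr, Flor, Fir);
  // trr[k] covers reflected points 0..k = original points n-1-k..n-1
  std::vector<double> tr(n);
  for (int j = 0; j < n; ++j) tr[j] = trr[n - 1 - j];
  double best = std::min(tr[0], tl[n - 1]);  // mode before/after all points
  for (int k = 0; k < n - 1; ++k) {
    double c = std::max(tl[k], tr[k + 1]);
    if (c < best) best = c;
  }
  return best;
}

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector xs, NumericVector ws) {
  const int n = xs.size();
  std::vector<double> x, w;
  x.reserve(n); w.reserve(n);
  double tot = 0.0;
  for (int i = 0; i < n; ++i) tot += ws[i];
  if (tot <= 0.0) stop("weights must have positive sum");
  for (int i = 0; i < n; ++i) {
    if (i > 0 && xs[i] <= xs[i - 1]) stop("x must be strictly increasing");
    if (ws[i] < 0) stop("weights must be non-negative");
    if (ws[i] > 0) {  // zero-weight points do not move the ECDF
      x.push_back(xs[i]);
      w.push_back(ws[i] / tot);
    }
  }
  if (x.empty()) stop("no positive weights");
  return dip_core(x, w);
}

// Null distribution of binned-PDF dips for uniform samples: draws n_samples
// uniforms, bins them into n_bins over the sample range, and computes the
// dip of the binned density; repeated n_null times. Uses R's RNG so results
// are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector dip_null_uniform_cpp(int n_samples, int n_bins, int n_null) {
  if (n_samples < 2 || n_bins < 2 || n_null < 1)
    stop("invalid null parameters");
  NumericVector out(n_null);
  std::vector<double> u(n_samples);
  std::vector<double> counts(n_bins);
  std::vector<double> x, w;
  for (int b = 0; b < n_null; ++b) {
    double lo = R_PosInf, hi = R_NegInf;
    for (int i = 0; i < n_samples; ++i) {
      u[i] = unif_rand();
      if (u[i] < lo) lo = u[i];
      if (u[i] > hi) hi = u[i];
    }
    double range = hi - lo;
    if (range <= 0) { out[b] = 0.5; continue; }
    std::fill(counts.begin(), counts.end(), 0.0);
    for (int i = 0; i < n_samples; ++i) {
      int bin = (int)((u[i] - lo) / range * n_bins);
      if (bin >= n_bins) bin = n_bins - 1;
      counts[bin] += 1.0;
    }
    x.clear(); w.clear();
    for (int j = 0; j < n_bins; ++j) {
      if (counts[j] > 0) {
        x.push_back(lo + (j + 0.5) * range / n_bins);
        w.push_back(counts[j] / n_samples);
      }
    }
    out[b] = dip_core(x, w);
  }
  return out;
}
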