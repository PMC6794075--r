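// Hartigans' dip statistic: the minimal sup-norm distance between the
// empirical CDF and the class of unimodal distribution functions.
//
// Derivation used here: a unimodal df G is convex left of its mode and
// concave right of it (an atom at the mode is allowed). Fixing which data
// values lie strictly left/right of the mode, the constraint |F - G| <= d
// collapses to point constraints at the distinct data values x_i with
// ECDF value F_i and left limit F_i^-:
//   convex side:  G(x_i) in [F_i - d, F_i^- + d], G convex increasing;
//   concave side: G(x_i) in [F_i - d, F_i^- + d], G concave increasing.
// A convex function through these bands exists iff the lower convex hull
// of the upper bounds dominates the lower bounds, which fails exactly when
// some interior point j between i1 < j < i2 satisfies
//   F_j - chord_{i1,i2}(F^-)(x_j) > 2 d,
// and symmetrically on the concave side with chords of F against F^-.
// Single-point bands additionally require 2 d >= F_i - F_i^- (the atom
// mass). The dip is therefore half the minimum over modal splits of the
// maximal violation. Splits place the mode at a data value (absorbing its
// atom into the modal jump) or strictly between values.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

// For points (x[i], yh[i]) maintain the lower convex hull incrementally
// and record, for each prefix length k, the largest deviation
// ya[j] - hull_k(x_j) over interior points j (0-based arrays).
// out[k] (k = 0..m) = max over triples i1 < j < i2 <= k (1-based).
static void prefixTripleMax(const std::vector<double>& x,
                            const std::vector<double>& yh,
                            const std::vector<double>& ya,
                            std::vector<double>& out) {
  const int m = (int)x.size();
  out.assign(m + 1, 0.0);
  std::vector<int> hull;
  hull.reserve(m);
  double cur = 0.0;
  for (int k = 0; k < m; ++k) {
    while (hull.size() >= 2) {
      int h1 = hull[hull.size() - 2], h2 = hull[hull.size() - 1];
      // pop h2 if it lies on or above the chord h1 -> k
      double lhs = (yh[h2] - yh[h1]) * (x[k] - x[h1]);
      double rhs = (yh[k] - yh[h1]) * (x[h2] - x[h1]);
      if (lhs >= rhs) hull.pop_back(); else break;
    }
    if (!hull.empty()) {
      int t = hull.back();
      double dx = x[k] - x[t];
      for (int j = t + 1; j < k; ++j) {
        double line = yh[t] + (yh[k] - yh[t]) * (x[j] - x[t]) / dx;
        double dev = ya[j] - line;
        if (dev > cur) cur = dev;
      }
    }
    hull.push_back(k);
    out[k + 1] = cur;
  }
}

// dip of a sorted sample
static double dipSorted(const std::vector<double>& xs) {
  const int n = (int)xs.size();
  if (n <= 1) return 0.0;
  // collapse ties into distinct values with ECDF value F and left limit Fm
  std::vector<double> x, F, Fm, w;
  int i = 0;
  int cum = 0;
  while (i < n) {
    int j = i;
    while (j < n && xs[j] == xs[i]) ++j;
    x.push_back(xs[i]);
    Fm.push_back((double)cum / n);
    cum += (j - i);
    F.push_back((double)cum / n);
    w.push_back((double)(j - i) / n);
    i = j;
  }
  const int m = (int)x.size();
  if (m == 1) return 0.0;

  // prefix (convex-side) violations: hull of F^-, deviations of F
  std::vector<double> Cpre;
  prefixTripleMax(x, Fm, F, Cpre);

  // suffix (concave-side) violations via mirror transform
  std::vector<double> xr(m), yhr(m), yar(m);
  for (int k = 0; k < m; ++k) {
    xr[k] = -x[m - 1 - k];
    yhr[k] = -F[m - 1 - k];   // hull of F (upper) becomes lower hull
    yar[k] = -Fm[m - 1 - k];  // deviations of F^-
  }
  std::vector<double> Drev;
  prefixTripleMax(xr, yhr, yar, Drev);
  // Dsuf[k] (1-based, side = points k..m) = Drev[m - k + 1]

  std::vector<double> Wpre(m + 1, 0.0), Wsuf(m + 2, 0.0);
  for (int k = 1; k <= m; ++k)
    Wpre[k] = std::max(Wpre[k - 1], w[k - 1]);
  for (int k = m; k >= 1; --k)
    Wsuf[k] = std::max(Wsuf[k + 1], w[k - 1]);

  double best = R_PosInf;
  // mode strictly between values (or outside the range): split after k
  for (int k = 0; k <= m; ++k) {
    double d = std::max(std::max(Wpre[k], Cpre[k]),
                        std::max(Wsuf[k + 1],
                                 (k + 1 <= m) ? Drev[m - k] : 0.0));
    if (d < best) best = d;
  }
  // mode at value j: its atom is absorbed by the modal jump
  for (int j = 1; j <= m; ++j) {
    double ds = (j + 1 <= m) ? Drev[m - j] : 0.0;
    double d = std::max(std::max(Wpre[j - 1], Cpre[j - 1]),
                        std::max(Wsuf[j + 1], ds));
    if (d < best) best = d;
  }
  return best / 2.0;
}

} // namespace

//' @rdname dipStatistic
//' @name dip_stat_cpp
//' @keywords internal
// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector x) {
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  return dipSorted(xs);
}

// Monte-Carlo null: dips of `nboot` uniform(0,1) samples of size n.
// Uses R's RNG, so set.seed() controls reproducibility.
// [[Rcpp::export(name = ".dip_null_cpp")]]
NumericVector dip_null_cpp(int n, int nboot) {
  NumericVector out(nboot);
  std::vector<double> xs(n);
  for (int b = 0; b < nboot; ++b) {
    for (int i = 0; i < n; ++i) xs[i] = unif_rand();
    std::sort(xs.begin(), xs.end());
    out[b] = dipSorted(xs);
  }
  return out;
}
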