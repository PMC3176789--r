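#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double logaddexp(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + log1p(std::exp(-std::fabs(a - b)));
}

// Exact (up to lattice binning) distribution of the information content of a
// single alignment column of n letters drawn i.i.d. from `bg`, computed by
// dynamic programming over bases entirely in log space.  The column score is
//   I = sum_b (n_b/n) * log2( (n_b/n) / bg_b ),
// i.e. the KL divergence of the empirical column composition from the
// background, in bits.  Scores are rounded to the nearest multiple of
// bin_width.  Returns log P(bin) with attribute "min_bin" (lowest bin index;
// bin value = index * bin_width).
// [[Rcpp::export]]
NumericVector cpp_column_info_logdist(int n, NumericVector log_bg,
                                      double bin_width) {
  const int B = log_bg.size();
  if (n < 1) stop("n must be >= 1");
  if (B < 2) stop("need at least two letters in the background");
  const double ln2 = std::log(2.0);

  // per-base, per-count score bins and log weights p_b^k / k!
  std::vector< std::vector<int> > tb(B, std::vector<int>(n + 1));
  std::vector< std::vector<double> > lw(B, std::vector<double>(n + 1));
  for (int b = 0; b < B; ++b) {
    for (int k = 0; k <= n; ++k) {
      double t = 0.0;
      if (k > 0) {
        double x = (double)k / n;
        t = x * (std::log(x) - log_bg[b]) / ln2;
      }
      tb[b][k] = (int)std::llround(t / bin_width);
      lw[b][k] = k * log_bg[b] - std::lgamma(k + 1.0);
    }
  }

  // global bin range for partial sums (superset of the reachable range)
  int lo = 0, hi = 0;
  for (int b = 0; b < B; ++b) {
    int mn = 0, mx = 0;
    for (int k = 0; k <= n; ++k) {
      if (tb[b][k] < mn) mn = tb[b][k];
      if (tb[b][k] > mx) mx = tb[b][k];
    }
    lo += mn;
    hi += mx;
  }
  const int nb = hi - lo + 1;
  if ((double)(n + 1) * nb > 5e7)
    stop("state lattice too large; increase bin_width");

  std::vector<double> cur((size_t)(n + 1) * nb, R_NegInf);
  std::vector<double> nxt;
  cur[(size_t)0 * nb + (0 - lo)] = 0.0;  // 0 letters placed, score 0

  for (int b = 0; b < B - 1; ++b) {
    nxt.assign((size_t)(n + 1) * nb, R_NegInf);
    for (int m = 0; m <= n; ++m) {
      const double* src = &cur[(size_t)m * nb];
      for (int s = 0; s < nb; ++s) {
        double v = src[s];
        if (v == R_NegInf) continue;
        for (int k = 0; k <= n - m; ++k) {
          int s2 = s + tb[b][k];
          double* dst = &nxt[(size_t)(m + k) * nb];
          dst[s2] = logaddexp(dst[s2], v + lw[b][k]);
        }
      }
    }
    cur.swap(nxt);
  }

  // last base: count forced to n - m
  std::vector<double> out(nb, R_NegInf);
  const int bl = B - 1;
  for (int m = 0; m <= n; ++m) {
    const int k = n - m;
    const double w = lw[bl][k];
    const int sh = tb[bl][k];
    const double* src = &cur[(size_t)m * nb];
    for (int s = 0; s < nb; ++s) {
      double v = src[s];
      if (v == R_NegInf) continue;
      int s2 = s + sh;
      out[s2] = logaddexp(out[s2], v + w);
    }
  }

  const double lfn = std::lgamma(n + 1.0);
  int first = -1, last = -1;
  for (int s = 0; s < nb; ++s) {
    if (out[s] != R_NegInf) {
      if (first < 0) first = s;
      last = s;
    }
  }
  if (first < 0) stop("internal error: empty distribution");
  NumericVector res(last - first + 1);
  for (int s = first; s <= last; ++s)
    res[s - first] = (out[s] == R_NegInf) ? R_NegInf : out[s] + lfn;
  res.attr("min_bin") = lo + first;
  return res;
}

// Log-space convolution of two binned log-probability vectors.
// [[Rcpp::export]]
NumericVector cpp_logconv(NumericVector la, NumericVector lb) {
  const int na = la.size(), nb = lb.size();
  NumericVector out(na + nb - 1, R_NegInf);
  for (int i = 0; i < na; ++i) {
    double a = la[i];
    if (a == R_NegInf) continue;
    for (int j = 0; j < nb; ++j) {
      double b = lb[j];
      if (b == R_NegInf) continue;
      out[i + j] = logaddexp(out[i + j], a + b);
    }
  }
  return out;
}
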