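#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman-Moorman convention):
// over all pairs i < j of the N - m template vectors, B counts Chebyshev
// matches at length m and A matches at length m + 1, both within
// tolerance r (<=), self-matches excluded by construction.
// Template pairs are enumerated through the templates sorted by their
// first coordinate, so only pairs already matching on that coordinate are
// inspected (a sliding window over the sorted order); the counts are
// identical to the naive double loop over all i < j.
// [[Rcpp::export(name = ".sampenCounts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;          // number of templates of length m (and m+1)
  if (nt < 2) stop("series too short for the requested embedding length");
  std::vector<int> idx(nt);
  for (int i = 0; i < nt; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  double A = 0.0, B = 0.0;
  for (int a = 0; a < nt - 1; ++a) {
    const int i = idx[a];
    for (int b = a + 1; b < nt && x[idx[b]] - x[i] <= r; ++b) {
      const int j = idx[b];
      bool match = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}

// Rescaled range R/S per disjoint window of width w taken from the start
// of the series: range of the cumulative mean-deviation profile
// (including its zero origin) divided by the sample SD of the window.
// Windows with zero SD yield NaN.
// [[Rcpp::export(name = ".rsPartition")]]
NumericVector rs_partition(NumericVector x, int w) {
  const int nw = x.size() / w;
  NumericVector out(nw);
  for (int b = 0; b < nw; ++b) {
    const double* z = &x[b * w];
    double mean = 0.0;
    for (int i = 0; i < w; ++i) mean += z[i];
    mean /= w;
    double y = 0.0, ymin = 0.0, ymax = 0.0, ss = 0.0;
    for (int i = 0; i < w; ++i) {
      const double d = z[i] - mean;
      ss += d * d;
      y += d;
      if (y < ymin) ymin = y;
      if (y > ymax) ymax = y;
    }
    const double sd = std::sqrt(ss / (w - 1));
    out[b] = (sd == 0.0) ? NA_REAL : (ymax - ymin) / sd;
  }
  return out;
}

// Higuchi average curve lengths L(k) for k = 1..kmax:
// L(m,k) = [ sum_{i=1}^{M} |x(m+ik) - x(m+(i-1)k)| ] * (N-1) / (M*k) / k,
// with M = floor((N-m)/k), averaged over the k offsets m = 1..k.
// [[Rcpp::export(name = ".higuchiLengths")]]
NumericVector higuchi_lengths(NumericVector x, int kmax) {
  const int n = x.size();
  if (n < 2 * kmax) stop("series must be at least 2 * kmax samples long");
  NumericVector L(kmax);
  for (int k = 1; k <= kmax; ++k) {
    double Lk = 0.0;
    for (int m = 1; m <= k; ++m) {
      const int M = (n - m) / k;
      if (M < 1) continue;
      double s = 0.0;
      for (int i = 1; i <= M; ++i)
        s += std::fabs(x[m + i * k - 1] - x[m + (i - 1) * k - 1]);
      Lk += s * (double)(n - 1) / ((double)M * k) / (double)k;
    }
    L[k - 1] = Lk / k;
  }
  return L;
}
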