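#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Binned cross-correlogram pair counts between two sorted spike trains.
// Lags d = tj - ti are assigned to bins centred at k * bin_s for
// k = -L..L with L = round(max_lag_s / bin_s); bin membership is
// round-half-away-from-zero, so each bin covers [k*bin - bin/2, k*bin + bin/2).
// When exclude_self is true, pairs with identical indices are skipped
// (used for autocorrelograms of a train against itself).
// [[Rcpp::export]]
IntegerVector cc_counts_cpp(NumericVector ti, NumericVector tj,
                            double bin_s, double max_lag_s, bool exclude_self) {
  const int L = (int)std::lround(max_lag_s / bin_s);
  IntegerVector counts(2 * L + 1);
  const int ni = ti.size(), nj = tj.size();
  const double win = (L + 0.5) * bin_s;  // edge bins are full width
  int jlo = 0;
  for (int a = 0; a < ni; ++a) {
    const double t = ti[a];
    while (jlo < nj && tj[jlo] < t - win) ++jlo;
    for (int b = jlo; b < nj; ++b) {
      const double d = tj[b] - t;
      if (d >= win) break;
      if (exclude_self && b == a) continue;
      const long k = std::lround(d / bin_s);
      if (k < -L || k > L) continue;
      counts[(int)k + L]++;
    }
  }
  return counts;
}
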