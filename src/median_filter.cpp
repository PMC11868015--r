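#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Median of a windowed neighbourhood around each beat, centre excluded.
// Edges use truncated windows. half_window = beats on each side.
// [[Rcpp::export(name = ".windowed_median_excl")]]
NumericVector windowed_median_excl(NumericVector rr, int half_window) {
  int n = rr.size();
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(2 * half_window);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - half_window);
    int hi = std::min(n - 1, i + half_window);
    buf.clear();
    for (int j = lo; j <= hi; ++j)
      if (j != i) buf.push_back(rr[j]);
    int m = buf.size();
    if (m == 0) { out[i] = rr[i]; continue; }
    int k = m / 2;
    std::nth_element(buf.begin(), buf.begin() + k, buf.end());
    double med = buf[k];
    if (m % 2 == 0) {
      // lower middle is the max of the first half after partitioning
      double lo_mid = *std::max_element(buf.begin(), buf.begin() + k);
      med = 0.5 * (med + lo_mid);
    }
    out[i] = med;
  }
  return out;
}
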