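#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of a scratch vector (modified in place)
static double med_of(std::vector<double>& v) {
  const size_t n = v.size();
  std::sort(v.begin(), v.end());
  if (n % 2 == 1) return v[n / 2];
  return (v[n / 2 - 1] + v[n / 2]) / 2.0;
}

// Sliding-window Hampel identifier over full centred windows (the
// leading/trailing half_window samples are passed through unflagged)
// with NA-excluding window statistics; robust spread = 1.4826 * MAD,
// replacement by the window median.
// [[Rcpp::export]]
List hampel_core(NumericVector x, int half_window, double k) {
  const int n = x.size();
  NumericVector y = clone(x);
  std::vector<int> flagged;
  bool starved = false;
  std::vector<double> w, dev;
  w.reserve(2 * half_window + 1);
  dev.reserve(2 * half_window + 1);
  for (int i = half_window; i < n - half_window; ++i) {
    if (NumericVector::is_na(x[i])) continue;
    w.clear();
    const int lo = i - half_window;
    const int hi = i + half_window;
    for (int j = lo; j <= hi; ++j)
      if (!NumericVector::is_na(x[j])) w.push_back(x[j]);
    if (w.size() <= 1) { starved = true; continue; }
    dev = w;
    const double m = med_of(dev);  // dev now sorted copy of w
    for (size_t j = 0; j < dev.size(); ++j) dev[j] = std::fabs(w[j] - m);
    // NB: w itself was not sorted; dev recomputed from unsorted values
    const double s = 1.4826 * med_of(dev);
    if (std::fabs(x[i] - m) > k * s) {
      y[i] = m;
      flagged.push_back(i + 1);  // 1-based for R
    }
  }
  return List::create(_["filtered"] = y,
                      _["flagged"] = wrap(flagged),
                      _["starved"] = starved);
}
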