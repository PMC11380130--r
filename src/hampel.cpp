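#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Exact Hampel filter with a centered window, symmetric truncation at the
// edges. Window bounds are monotone in i, so the sorted window is maintained
// incrementally. The rejection test |x_i - med| > kc * MAD (kc = threshold *
// 1.4826) is evaluated without materialising the MAD: MAD < q/kc iff at
// least h = (w+1)/2 window elements have kc * |S_j - med| < q, and because
// the window is sorted that count comes from two binary searches. The
// predicate uses the same products as the naive definition, so results are
// bit-identical to the brute-force per-window median/MAD filter.
// [[Rcpp::export(name = ".hampel_cpp")]]
NumericVector hampel_cpp(NumericVector x, int window, double threshold) {
  const int n = x.size();
  const int half = window / 2;
  NumericVector out(clone(x));
  if (n == 0) return out;

  const double kc = threshold * 1.4826;
  std::vector<double> S; // sorted current window
  S.reserve(2 * half + 2);
  int L = 0, R = -1; // current window bounds [L, R]

  for (int i = 0; i < n; ++i) {
    int k = std::min(half, std::min(i, n - 1 - i));
    int Li = i - k, Ri = i + k;
    while (R < Ri) { // bounds are non-decreasing in i
      ++R;
      S.insert(std::upper_bound(S.begin(), S.end(), x[R]), x[R]);
    }
    while (L < Li) {
      S.erase(std::lower_bound(S.begin(), S.end(), x[L]));
      ++L;
    }
    const int sz = (int)S.size(); // 2k + 1, odd
    const int hm = sz / 2;        // median index; h = hm + 1
    const double med = S[hm];
    const double q = std::abs(x[i] - med);
    if (q == 0.0) continue; // never exceeds a non-negative threshold
    // count elements with kc * |S_j - med| < q
    // right half: deviations S[j] - med non-decreasing for j >= hm
    int lo = hm, hi = sz; // find first j in [hm, sz) failing the predicate
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (kc * (S[mid] - med) < q) lo = mid + 1; else hi = mid;
    }
    int cnt = lo - hm; // includes the median itself (deviation 0)
    // left half: deviations med - S[j] non-increasing for j <= hm
    lo = 0; hi = hm; // find first j in [0, hm) satisfying the predicate
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (kc * (med - S[mid]) < q) hi = mid; else lo = mid + 1;
    }
    cnt += hm - lo;
    if (cnt >= hm + 1) out[i] = med; // kc * MAD < q  =>  spike, replace
  }
  return out;
}
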