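#include <Rcpp.h>
using namespace Rcpp;

// Sliding-window spherical I-DT scan.
//
// t: sample timestamps (ms, strictly increasing); V: n x 3 unit gaze vectors;
// cosmax: cosine of the dispersion threshold (pairwise great-circle angle);
// min_duration: minimum window span in ms; dt: nominal sample period used to
// close the final half-open interval.
//
// Returns one row per fixation: start, end, and the unnormalized vector sum
// of the window samples (the caller projects it back to the sphere).
// [[Rcpp::export]]
NumericMatrix idt_scan(NumericVector t, NumericMatrix V, double cosmax,
                       double min_duration, double dt) {
  const int n = t.size();
  std::vector<double> out;
  int i = 0, j = 0;
  while (true) {
    if (j < i) j = i;
    while (j < n && t[j] - t[i] < min_duration) ++j;
    if (j >= n) break;
    bool ok = true;
    for (int a = i; a <= j && ok; ++a) {
      for (int b = a + 1; b <= j; ++b) {
        const double d = V(a, 0) * V(b, 0) + V(a, 1) * V(b, 1) +
                         V(a, 2) * V(b, 2);
        if (d < cosmax) { ok = false; break; }
      }
    }
    if (ok) {
      int k = j;
      while (k < n - 1) {
        bool fits = true;
        for (int a = i; a <= k; ++a) {
          const double d = V(a, 0) * V(k + 1, 0) + V(a, 1) * V(k + 1, 1) +
                           V(a, 2) * V(k + 1, 2);
          if (d < cosmax) { fits = false; break; }
        }
        if (!fits) break;
        ++k;
      }
      double sx = 0, sy = 0, sz = 0;
      for (int a = i; a <= k; ++a) {
        sx += V(a, 0); sy += V(a, 1); sz += V(a, 2);
      }
      const double end = (k < n - 1) ? t[k + 1] : t[k] + dt;
      out.push_back(t[i]); out.push_back(end);
      out.push_back(sx);   out.push_back(sy);  out.push_back(sz);
      i = k + 1; j = i;
    } else {
      ++i;
    }
  }
  const int m = static_cast<int>(out.size() / 5);
  NumericMatrix res(m, 5);
  for (int r = 0; r < m; ++r)
    for (int c = 0; c < 5; ++c) res(r, c) = out[r * 5 + c];
  return res;
}
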