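// Phase-space nearest-neighbour rearrangement of a trial ensemble: for each
// reference time point on the ensemble-mean (y, z) trajectory and each trial,
// find the trial sample inside a window of T_w points centred on the
// reference index that minimises the Euclidean distance in the (y, z) plane.
// Ties break to the smallest index.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List match_nn(NumericVector ref_y, NumericVector ref_z,
              NumericMatrix trial_y, NumericMatrix trial_z, int T_w) {
  const int T = ref_y.size();
  const int n = trial_y.ncol();
  if (trial_y.nrow() != T || trial_z.nrow() != T)
    stop("match_nn: trials must share the reference grid length");
  const int half = T_w / 2;
  IntegerMatrix idx(T, n);
  NumericMatrix dist(T, n);
  for (int k = 0; k < n; ++k) {
    for (int t = 0; t < T; ++t) {
      int lo = t - half; if (lo < 0) lo = 0;
      int hi = t + half; if (hi > T - 1) hi = T - 1;
      double best = R_PosInf;
      int bi = lo;
      for (int s = lo; s <= hi; ++s) {
        double dy = trial_y(s, k) - ref_y[t];
        double dz = trial_z(s, k) - ref_z[t];
        double d2 = dy * dy + dz * dz;
        if (d2 < best) { best = d2; bi = s; }
      }
      idx(t, k) = bi + 1;          // 1-based for R
      dist(t, k) = std::sqrt(best);
    }
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
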