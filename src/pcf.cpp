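#include <Rcpp.h>
using namespace Rcpp;

// Exact least-squares piecewise-constant fit with a per-breakpoint penalty.
// Minimizes  sum_segments sum_i (x_i - mean_seg)^2 + gamma * (#breakpoints)
// by O(n^2) dynamic programming over the last-segment start. Ties in the
// objective are broken toward fewer segments, then toward an earlier start
// of the last segment, so the output is deterministic.
// [[Rcpp::export]]
List pcf_dp(NumericVector x, double gamma) {
  const int n = x.size();
  std::vector<double> S(n + 1, 0.0), S2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    S[i + 1] = S[i] + x[i];
    S2[i + 1] = S2[i] + x[i] * x[i];
  }
  std::vector<double> inv_len(n + 1, 0.0);
  for (int l = 1; l <= n; ++l) inv_len[l] = 1.0 / l;
  std::vector<double> best(n + 1, 0.0);
  std::vector<int> prev(n + 1, 0), nseg(n + 1, 0);
  for (int j = 1; j <= n; ++j) {
    const double Sj = S[j], S2j = S2[j];
    double bv = R_PosInf;
    int bi = 1, bn = 0;
    for (int i = 1; i <= j; ++i) {
      const double s = Sj - S[i - 1];
      const double sse = (S2j - S2[i - 1]) - s * s * inv_len[j - i + 1];
      const double cost = best[i - 1] + sse + (i > 1 ? gamma : 0.0);
      if (cost < bv) {
        bv = cost;
        bi = i;
        bn = (i > 1 ? nseg[i - 1] : 0) + 1;
      } else if (cost == bv) {
        const int cn = (i > 1 ? nseg[i - 1] : 0) + 1;
        if (cn < bn || (cn == bn && i < bi)) {
          bi = i;
          bn = cn;
        }
      }
    }
    best[j] = bv;
    prev[j] = bi;
    nseg[j] = bn;
  }
  const int k = nseg[n];
  IntegerVector first(k), last(k);
  NumericVector mean(k);
  int j = n;
  for (int s = k - 1; s >= 0; --s) {
    const int i = prev[j];
    first[s] = i - 1;  // 0-based
    last[s] = j - 1;
    mean[s] = (S[j] - S[i - 1]) / (j - i + 1);
    j = i - 1;
  }
  return List::create(_["first"] = first, _["last"] = last,
                      _["mean"] = mean, _["objective"] = best[n]);
}
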