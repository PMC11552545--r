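#include <Rcpp.h>
using namespace Rcpp;

// Perievent SDO extraction over a stack of spike trains (e.g. the observed
// train plus its shuffled surrogates). For each column of `bins` (one
// train of spike sample indices, 1-based) it computes
//   L     = (1/k) * (P1 P0' - diag(rowSums(P0)))   (raw SDO, column-major)
//   joint = (1/k) *  P1 P0'                        (mean joint distribution)
//   p0bar, p1bar = ensemble-average pre/post distributions
//   p_at  = distribution of the state in the spike bin
// Windows are (s - pre, s] and (s, s + post]; spikes whose windows cross
// the boundary are skipped and k adjusted.
// [[Rcpp::export]]
List perievent_stack_cpp(IntegerVector states, IntegerMatrix bins,
                         int n_states, int pre, int post) {
  const int T = states.size();
  const int k_max = bins.nrow();
  const int S = bins.ncol();
  const int n = n_states;

  NumericMatrix L(n * n, S), joint(n * n, S);
  NumericMatrix p0bar(n, S), p1bar(n, S), p_at(n, S);
  IntegerVector k_used(S);

  std::vector<int> c0(n), c1(n), u0(n), u1(n);

  for (int s = 0; s < S; ++s) {
    double *Ls = &L(0, s);
    double *Js = &joint(0, s);
    double *b0 = &p0bar(0, s);
    double *b1 = &p1bar(0, s);
    double *pa = &p_at(0, s);
    int k = 0;
    for (int i = 0; i < k_max; ++i) {
      int c = bins(i, s);          // 1-based spike bin
      if (c == NA_INTEGER) continue;
      if (c - pre + 1 < 1 || c + post > T) continue;
      // sparse window histograms: track touched states only
      int m0 = 0, m1 = 0;
      for (int t = c - pre; t < c; ++t) {              // (s-pre, s]
        int v = states[t] - 1;
        if (c0[v]++ == 0) u0[m0++] = v;
      }
      for (int t = c; t < c + post; ++t) {             // (s, s+post]
        int v = states[t] - 1;
        if (c1[v]++ == 0) u1[m1++] = v;
      }
      pa[states[c - 1] - 1] += 1.0;
      for (int a = 0; a < m0; ++a) {
        int j = u0[a];
        double w = (double)c0[j] / pre;
        b0[j] += w;
        double *col = Ls + j * n;
        double *jcol = Js + j * n;
        for (int b = 0; b < m1; ++b) {
          int r = u1[b];
          double add = w * (double)c1[r] / post;
          col[r] += add;
          jcol[r] += add;
        }
        col[j] -= w;               // diag(p0) term
      }
      for (int b = 0; b < m1; ++b) b1[u1[b]] += (double)c1[u1[b]] / post;
      for (int a = 0; a < m0; ++a) c0[u0[a]] = 0;
      for (int b = 0; b < m1; ++b) c1[u1[b]] = 0;
      ++k;
    }
    k_used[s] = k;
    if (k > 0) {
      double inv = 1.0 / k;
      for (int e = 0; e < n * n; ++e) { Ls[e] *= inv; Js[e] *= inv; }
      for (int r = 0; r < n; ++r) { b0[r] *= inv; b1[r] *= inv; pa[r] *= inv; }
    }
  }
  return List::create(_["L"] = L, _["joint"] = joint, _["p0_bar"] = p0bar,
                      _["p1_bar"] = p1bar, _["p_at_spike"] = p_at,
                      _["k_used"] = k_used);
}

// states[t] (1-based values) gathered in the spike bins; R indexing helper
// used by tests to keep the two routes honest.
// [[Rcpp::export]]
IntegerVector states_at_cpp(IntegerVector states, IntegerVector bins) {
  IntegerVector out(bins.size());
  for (int i = 0; i < bins.size(); ++i) out[i] = states[bins[i] - 1];
  return out;
}
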