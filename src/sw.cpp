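#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman. Gap of length g costs open + (g-1)*extend,
// i.e. `open` is charged for the first gap character. Sequences are 0-based
// integer codes into the substitution matrix.

static const int NEG = -1000000000;

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector q, IntegerVector t, IntegerMatrix S,
                  int gap_open, int gap_extend) {
  const int m = q.size(), n = t.size();
  // full DP tables for traceback; fragments are short (q <= ~20 aa)
  IntegerMatrix H(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);
  for (int j = 0; j <= n; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= m; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // E: gap in query (consume t), F: gap in target (consume q)
      int e = std::max(H(i, j - 1) - gap_open, E(i, j - 1) - gap_extend);
      int f = std::max(H(i - 1, j) - gap_open, F(i - 1, j) - gap_extend);
      int d = H(i - 1, j - 1) + S(q[i - 1], t[j - 1]);
      int h = std::max(0, std::max(d, std::max(e, f)));
      E(i, j) = e; F(i, j) = f; H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }  // first max: smallest i,j
    }
  }
  // traceback from (bi,bj); prefer diagonal, then F (gap in t), then E
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    if (state == 0) {
      int h = H(i, j);
      if (h == 0) break;
      if (h == H(i - 1, j - 1) + S(q[i - 1], t[j - 1])) { --i; --j; }
      else if (h == F(i, j)) state = 2;
      else state = 1;
    } else if (state == 1) {
      if (E(i, j) == H(i, j - 1) - gap_open) { --j; state = 0; }
      else { --j; }
    } else {
      if (F(i, j) == H(i - 1, j) - gap_open) { --i; state = 0; }
      else { --i; }
    }
  }
  return List::create(_["score"] = best,
                      _["q_start"] = i, _["q_end"] = bi,
                      _["t_start"] = j, _["t_end"] = bj);
}

// Score-only batch version (linear space) for null simulations.
// [[Rcpp::export(name = ".sw_scores_cpp")]]
IntegerVector sw_scores_cpp(List qs, List ts, IntegerMatrix S,
                            int gap_open, int gap_extend) {
  const int N = qs.size();
  IntegerVector out(N);
  for (int k = 0; k < N; ++k) {
    IntegerVector q = qs[k], t = ts[k];
    const int m = q.size(), n = t.size();
    std::vector<int> H(n + 1, 0), E(n + 1, NEG);
    int best = 0;
    for (int i = 1; i <= m; ++i) {
      int diag = 0;     // H[i-1][j-1]
      int f = NEG;      // F[i][j] running along the row
      for (int j = 1; j <= n; ++j) {
        int e = std::max(H[j] - gap_open, E[j] - gap_extend); // uses H[i-1][j]
        // NOTE: E indexed by column j tracks gaps in the QUERY here
        // (vertical); F tracks horizontal. Symmetric costs make the
        // orientation irrelevant for the score.
        f = std::max((j > 1 ? H[j - 1] : 0) - gap_open, f - gap_extend);
        int d = diag + S(q[i - 1], t[j - 1]);
        diag = H[j];
        int h = std::max(0, std::max(d, std::max(e, f)));
        E[j] = e; H[j] = h;
        if (h > best) best = h;
      }
    }
    out[k] = best;
  }
  return out;
}
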