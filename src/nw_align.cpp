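#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty.
//
// Bicriteria DP: optimal score first, then the maximum number of matched
// columns among score-optimal alignments. Both criteria are additive, so the
// lexicographic optimum decomposes cell-wise. This makes the reported match
// count canonical: it depends only on the input pair, not on traceback
// order, so percent identity is symmetric under swapping the inputs.
//
// Traceback tie-break priority: diagonal > up (gap in b) > left (gap in a),
// applied at every cell so the alignment itself is deterministic too.
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  NumericMatrix F(n + 1, m + 1);
  IntegerMatrix M(n + 1, m + 1);   // max matches among score-optimal prefixes
  for (int i = 1; i <= n; ++i) F(i, 0) = i * gap;
  for (int j = 1; j <= m; ++j) F(0, j) = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      bool eq = a[i - 1] == b[j - 1];
      double sub = F(i - 1, j - 1) + (eq ? match : mismatch);
      double up = F(i - 1, j) + gap;
      double left = F(i, j - 1) + gap;
      double best = std::max(sub, std::max(up, left));
      int bm = -1;
      if (sub == best) bm = std::max(bm, M(i - 1, j - 1) + (eq ? 1 : 0));
      if (up == best) bm = std::max(bm, M(i - 1, j));
      if (left == best) bm = std::max(bm, M(i, j - 1));
      F(i, j) = best;
      M(i, j) = bm;
    }
  }
  // traceback along (optimal score, max matches), diag > up > left on ties
  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    bool moved = false;
    if (i > 0 && j > 0) {
      bool eq = a[i - 1] == b[j - 1];
      if (F(i, j) == F(i - 1, j - 1) + (eq ? match : mismatch) &&
          M(i, j) == M(i - 1, j - 1) + (eq ? 1 : 0)) {
        ra.push_back(a[i - 1]);
        rb.push_back(b[j - 1]);
        --i; --j;
        moved = true;
      }
    }
    if (!moved && i > 0 && F(i, j) == F(i - 1, j) + gap &&
        M(i, j) == M(i - 1, j)) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
      moved = true;
    }
    if (!moved) {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = F(n, m));
}
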