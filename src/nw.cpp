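#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with match +1, mismatch 0 and a
// linear gap penalty. Traceback ties are resolved toward diagonal moves,
// then toward gaps in the second sequence, so the reported identity is
// deterministic. Returns the optimal score, the number of identical
// aligned positions on the traceback path, and the alignment length.
//
// [[Rcpp::export]]
List nw_align_stats(std::string a, std::string b,
                    double match = 1.0, double mismatch = 0.0,
                    double gap = -0.5) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  NumericMatrix S(n + 1, m + 1);
  // 0 = diagonal, 1 = up (gap in b), 2 = left (gap in a)
  IntegerMatrix P(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) { S(i, 0) = gap * i; P(i, 0) = 1; }
  for (int j = 1; j <= m; ++j) { S(0, j) = gap * j; P(0, j) = 2; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
      double up   = S(i - 1, j) + gap;
      double left = S(i, j - 1) + gap;
      double best = diag; int move = 0;
      if (up > best)   { best = up;   move = 1; }
      if (left > best) { best = left; move = 2; }
      S(i, j) = best;
      P(i, j) = move;
    }
  }

  int i = n, j = m, matches = 0, aln_len = 0;
  while (i > 0 || j > 0) {
    int move = P(i, j);
    if (move == 0) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (move == 1) {
      --i;
    } else {
      --j;
    }
    ++aln_len;
  }

  return List::create(_["score"] = S(n, m),
                      _["matches"] = matches,
                      _["length"] = aln_len);
}
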