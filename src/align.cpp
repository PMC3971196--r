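#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps over a precomputed
// column-score matrix, Gotoh three-state recursion. S(i, j) holds the score
// of aligning column i of profile A with column j of profile B, so the same
// kernel serves both residue-residue and profile-profile alignment. A gap of
// length k costs gap_open + k * gap_extend (both <= 0). Ties are broken
// deterministically: match/mismatch first, then a gap in B (consuming A),
// then a gap in A.
//
// Returns the optimal score and the traceback as a vector of moves from the
// start of the alignment: 1 = diagonal, 2 = consume A (gap in B),
// 3 = consume B (gap in A).

// [[Rcpp::export]]
List affine_align_dp(NumericMatrix S, double gap_open, double gap_extend) {
  const int m = S.nrow(), n = S.ncol();
  const double NEG = -1e100;
  // state 0 = M (diagonal), 1 = X (gap in B), 2 = Y (gap in A)
  NumericMatrix M(m + 1, n + 1), X(m + 1, n + 1), Y(m + 1, n + 1);
  IntegerMatrix pM(m + 1, n + 1), pX(m + 1, n + 1), pY(m + 1, n + 1);

  for (int i = 0; i <= m; ++i)
    for (int j = 0; j <= n; ++j) { M(i, j) = X(i, j) = Y(i, j) = NEG; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= m; ++i) { X(i, 0) = gap_open + i * gap_extend; pX(i, 0) = 1; }
  for (int j = 1; j <= n; ++j) { Y(0, j) = gap_open + j * gap_extend; pY(0, j) = 2; }
  pX(1, 0) = 0; // first gap opens from M(0,0)
  pY(0, 1) = 0;

  for (int i = 0; i <= m; ++i) {
    for (int j = 0; j <= n; ++j) {
      if (i > 0 && j > 0) {
        double best = M(i - 1, j - 1); int arg = 0;
        if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); arg = 1; }
        if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); arg = 2; }
        M(i, j) = best + S(i - 1, j - 1);
        pM(i, j) = arg;
      }
      if (i > 0 && (i > 1 || j > 0)) {
        double open = M(i - 1, j) + gap_open + gap_extend; int arg = 0;
        double ext = X(i - 1, j) + gap_extend;
        double cross = Y(i - 1, j) + gap_open + gap_extend;
        double best = open;
        if (ext > best) { best = ext; arg = 1; }
        if (cross > best) { best = cross; arg = 2; }
        if (best > X(i, j)) { X(i, j) = best; pX(i, j) = arg; }
      }
      if (j > 0 && (j > 1 || i > 0)) {
        double open = M(i, j - 1) + gap_open + gap_extend; int arg = 0;
        double ext = Y(i, j - 1) + gap_extend;
        double cross = X(i, j - 1) + gap_open + gap_extend;
        double best = open;
        if (ext > best) { best = ext; arg = 2; }
        if (cross > best) { best = cross; arg = 1; }
        if (best > Y(i, j)) { Y(i, j) = best; pY(i, j) = arg; }
      }
    }
  }

  int state = 0;
  double score = M(m, n);
  if (X(m, n) > score) { score = X(m, n); state = 1; }
  if (Y(m, n) > score) { score = Y(m, n); state = 2; }

  std::vector<int> moves;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (state == 0) {
      moves.push_back(1);
      state = pM(i, j); --i; --j;
    } else if (state == 1) {
      moves.push_back(2);
      state = pX(i, j); --i;
    } else {
      moves.push_back(3);
      state = pY(i, j); --j;
    }
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(_["score"] = score,
                      _["moves"] = IntegerVector(moves.begin(), moves.end()));
}
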