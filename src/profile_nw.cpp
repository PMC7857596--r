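#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment of two profiles under affine gaps.
// S is the n1 x n2 matrix of expected column-pair substitution scores.
// A gap of length L costs gapOpen + L * gapExt, matching the pairwise
// scheme's convention. Tie-break is fixed: prefer match, then a gap in
// the second profile, then a gap in the first.
//
// Returns two integer vectors of equal length giving, for each merged
// column, the source column in profile A and in profile B (0 = gap).
// [[Rcpp::export]]
List cpp_profile_nw(NumericMatrix S, double gapOpen, double gapExt) {
  const int n1 = S.nrow(), n2 = S.ncol();
  const double NEG = -1e30;
  const double openCost = gapOpen + gapExt;

  NumericMatrix M(n1 + 1, n2 + 1), X(n1 + 1, n2 + 1), Y(n1 + 1, n2 + 1);
  // pointer codes: 0 = from M, 1 = from X, 2 = from Y
  IntegerMatrix pm(n1 + 1, n2 + 1), px(n1 + 1, n2 + 1), py(n1 + 1, n2 + 1);

  for (int i = 0; i <= n1; ++i)
    for (int j = 0; j <= n2; ++j) { M(i, j) = X(i, j) = Y(i, j) = NEG; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n1; ++i) { X(i, 0) = -(gapOpen + i * gapExt); px(i, 0) = 1; }
  for (int j = 1; j <= n2; ++j) { Y(0, j) = -(gapOpen + j * gapExt); py(0, j) = 2; }

  for (int i = 1; i <= n1; ++i) {
    for (int j = 1; j <= n2; ++j) {
      // match state
      double bm = M(i - 1, j - 1); int pb = 0;
      if (X(i - 1, j - 1) > bm) { bm = X(i - 1, j - 1); pb = 1; }
      if (Y(i - 1, j - 1) > bm) { bm = Y(i - 1, j - 1); pb = 2; }
      M(i, j) = bm + S(i - 1, j - 1); pm(i, j) = pb;
      // gap in profile B (consume a column of A)
      double bx = M(i - 1, j) - openCost; int pxb = 0;
      if (X(i - 1, j) - gapExt > bx) { bx = X(i - 1, j) - gapExt; pxb = 1; }
      if (Y(i - 1, j) - openCost > bx) { bx = Y(i - 1, j) - openCost; pxb = 2; }
      X(i, j) = bx; px(i, j) = pxb;
      // gap in profile A (consume a column of B)
      double by = M(i, j - 1) - openCost; int pyb = 0;
      if (X(i, j - 1) - openCost > by) { by = X(i, j - 1) - openCost; pyb = 1; }
      if (Y(i, j - 1) - gapExt > by) { by = Y(i, j - 1) - gapExt; pyb = 2; }
      Y(i, j) = by; py(i, j) = pyb;
    }
  }

  int state = 0;
  double best = M(n1, n2);
  if (X(n1, n2) > best) { best = X(n1, n2); state = 1; }
  if (Y(n1, n2) > best) { best = Y(n1, n2); state = 2; }

  std::vector<int> pa, pb;
  int i = n1, j = n2;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = pm(i, j);
      pa.push_back(i); pb.push_back(j);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = px(i, j);
      pa.push_back(i); pb.push_back(0);
      --i; state = prev;
    } else {
      int prev = py(i, j);
      pa.push_back(0); pb.push_back(j);
      --j; state = prev;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["a"] = wrap(pa), _["b"] = wrap(pb),
                      _["score"] = best);
}
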