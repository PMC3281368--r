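#include <Rcpp.h>
using namespace Rcpp;

// Pairwise valid-site and mismatch counts for all rows of an integer
// alignment matrix (A,C,G,T = 1..4; gap/ambiguity = 0).  Pairwise deletion:
// a column counts for a pair only when both rows are in 1..4.
// [[Rcpp::export(name = "jc_pair_counts_cpp")]]
List jc_pair_counts_cpp(IntegerMatrix m) {
  int n = m.nrow(), L = m.ncol();
  IntegerMatrix valid(n, n), diff(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int v = 0, d = 0;
      for (int k = 0; k < L; ++k) {
        int a = m(i, k), b = m(j, k);
        if (a > 0 && b > 0) {
          ++v;
          if (a != b) ++d;
        }
      }
      valid(i, j) = valid(j, i) = v;
      diff(i, j) = diff(j, i) = d;
    }
  }
  return List::create(_["valid"] = valid, _["diff"] = diff);
}

// Global (Needleman-Wunsch) affine-gap alignment over a precomputed
// column-pair score matrix S (n x m): S(i,j) is the score of aligning
// column i of profile A with column j of profile B.  gap_open is the cost
// of the first gap position (in addition to gap_extend), gap_extend the
// cost of each gap position; both are <= 0.
//
// Returns the optimal path as a 2-column matrix of 1-based column indices
// (0 = gap) plus the score.  Ties are broken deterministically:
// match > gap-in-B > gap-in-A.
// [[Rcpp::export(name = "affine_dp_cpp")]]
List affine_dp_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  int n = S.nrow(), m = S.ncol();
  const double NEG = -1e18;
  // state 0 = M (diag), 1 = X (gap in B, consume A row i), 2 = Y (gap in A)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix tb(3 * (n + 1), m + 1); // traceback: previous state per cell/state
  M(0, 0) = 0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = gap_open + i * gap_extend;
    tb(1 * (n + 1) + i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = gap_open + j * gap_extend;
    tb(2 * (n + 1) + 0, j) = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M
      double best = M(i - 1, j - 1); int bs = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); bs = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); bs = 2; }
      M(i, j) = best + S(i - 1, j - 1);
      tb(0 * (n + 1) + i, j) = bs;
      // X: gap in B (move down)
      double xo = M(i - 1, j) + gap_open + gap_extend;
      double xe = X(i - 1, j) + gap_extend;
      double yo = Y(i - 1, j) + gap_open + gap_extend;
      best = xo; bs = 0;
      if (xe > best) { best = xe; bs = 1; }
      if (yo > best) { best = yo; bs = 2; }
      X(i, j) = best;
      tb(1 * (n + 1) + i, j) = bs;
      // Y: gap in A (move right)
      double ym = M(i, j - 1) + gap_open + gap_extend;
      double yx = X(i, j - 1) + gap_open + gap_extend;
      double ye = Y(i, j - 1) + gap_extend;
      best = ym; bs = 0;
      if (yx > best) { best = yx; bs = 1; }
      if (ye > best) { best = ye; bs = 2; }
      Y(i, j) = best;
      tb(2 * (n + 1) + i, j) = bs;
    }
  }
  double score = M(n, m); int state = 0;
  if (X(n, m) > score) { score = X(n, m); state = 1; }
  if (Y(n, m) > score) { score = Y(n, m); state = 2; }
  // traceback
  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int prev = tb(state * (n + 1) + i, j);
    if (state == 0) { pa.push_back(i); pb.push_back(j); --i; --j; }
    else if (state == 1) { pa.push_back(i); pb.push_back(0); --i; }
    else { pa.push_back(0); pb.push_back(j); --j; }
    state = prev;
  }
  int len = pa.size();
  IntegerMatrix path(len, 2);
  for (int k = 0; k < len; ++k) {
    path(k, 0) = pa[len - 1 - k];
    path(k, 1) = pb[len - 1 - k];
  }
  return List::create(_["score"] = score, _["path"] = path);
}
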