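// Dynamic-programming kernels: global affine profile alignment of a query
// against MSA columns, and Fitch parsimony cost of a labeled tree. Both are
// called many times per placement, hence compiled.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Global Needleman-Wunsch with affine gaps between a query (rows of the
// score matrix) and MSA columns. score(i, j) is precomputed in R. A gap of
// length L costs open + L * ext. Returns, for each MSA column, the 1-based
// query position aligned to it, or 0 for a gap; query-only insertion states
// are implicitly discarded by this encoding (keep-length contract).
// [[Rcpp::export(name = ".profile_nw")]]
IntegerVector profile_nw(NumericMatrix score, double open, double ext) {
  const int Q = score.nrow(), C = score.ncol();
  const double NEG = -1e30;
  // state matrices over (i = query prefix, j = column prefix)
  NumericMatrix M(Q + 1, C + 1), Ix(Q + 1, C + 1), Iy(Q + 1, C + 1);
  IntegerMatrix tbM(Q + 1, C + 1), tbIx(Q + 1, C + 1), tbIy(Q + 1, C + 1);
  M(0, 0) = 0; Ix(0, 0) = NEG; Iy(0, 0) = NEG;
  for (int i = 1; i <= Q; ++i) {          // query consumed, no column: Ix
    M(i, 0) = NEG; Iy(i, 0) = NEG;
    Ix(i, 0) = -open - ext * i;
    tbIx(i, 0) = (i == 1) ? 0 : 1;        // 0: from M, 1: extend
  }
  for (int j = 1; j <= C; ++j) {          // column consumed, gap in query: Iy
    M(0, j) = NEG; Ix(0, j) = NEG;
    Iy(0, j) = -open - ext * j;
    tbIy(0, j) = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= Q; ++i) {
    for (int j = 1; j <= C; ++j) {
      // M: align query i to column j
      double m0 = M(i - 1, j - 1), m1 = Ix(i - 1, j - 1), m2 = Iy(i - 1, j - 1);
      int which = 0; double best = m0;
      if (m1 > best) { best = m1; which = 1; }
      if (m2 > best) { best = m2; which = 2; }
      M(i, j) = best + score(i - 1, j - 1);
      tbM(i, j) = which;
      // Ix: query residue i unmatched (insertion relative to columns)
      double a = M(i - 1, j) - open - ext, b = Ix(i - 1, j) - ext;
      Ix(i, j) = (a >= b) ? a : b;
      tbIx(i, j) = (a >= b) ? 0 : 1;
      // Iy: column j unmatched (gap in query row)
      double c = M(i, j - 1) - open - ext, d = Iy(i, j - 1) - ext;
      Iy(i, j) = (c >= d) ? c : d;
      tbIy(i, j) = (c >= d) ? 0 : 1;
    }
  }
  // traceback from the best final state
  int state = 0; double best = M(Q, C);
  if (Ix(Q, C) > best) { best = Ix(Q, C); state = 1; }
  if (Iy(Q, C) > best) { best = Iy(Q, C); state = 2; }
  IntegerVector out(C);
  int i = Q, j = C;
  while (i > 0 || j > 0) {
    if (state == 0) {
      out[j - 1] = i;
      int prev = tbM(i, j);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tbIx(i, j);
      --i; state = (prev == 1) ? 1 : 0;
    } else {
      out[j - 1] = 0;
      int prev = tbIy(i, j);
      --j; state = (prev == 1) ? 1 : 0;
    }
  }
  return out;
}

// Fitch parsimony cost over bitmask-encoded characters. children: list of
// integer vectors (1-based node ids; empty for leaves), postorder: node ids
// with children before parents, masks: sites x nodes integer matrix with
// leaf columns filled (gap/unknown = full mask). Internal columns are
// computed locally. Returns the total substitution count.
// [[Rcpp::export(name = ".fitch_cost")]]
int fitch_cost(List children, IntegerVector postorder, IntegerMatrix masks) {
  const int L = masks.nrow();
  const int n_nodes = masks.ncol();
  std::vector<int> work(static_cast<size_t>(L) * n_nodes);
  for (int v = 0; v < n_nodes; ++v)
    for (int s = 0; s < L; ++s)
      work[static_cast<size_t>(v) * L + s] = masks(s, v);
  int cost = 0;
  for (int k = 0; k < postorder.size(); ++k) {
    int node = postorder[k] - 1;
    IntegerVector ch = children[node];
    if (ch.size() == 0) continue;
    int* acc = &work[static_cast<size_t>(node) * L];
    int* first = &work[static_cast<size_t>(ch[0] - 1) * L];
    for (int s = 0; s < L; ++s) acc[s] = first[s];
    for (int c = 1; c < ch.size(); ++c) {
      int* cm = &work[static_cast<size_t>(ch[c] - 1) * L];
      for (int s = 0; s < L; ++s) {
        int inter = acc[s] & cm[s];
        if (inter) acc[s] = inter;
        else { acc[s] = acc[s] | cm[s]; ++cost; }
      }
    }
  }
  return cost;
}
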