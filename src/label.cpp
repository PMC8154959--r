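#include <Rcpp.h>
using namespace Rcpp;

// Two-pass union-find labeling of a binary raster.
// connectivity: 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
// Labels are renumbered 1..n in order of first appearance in column-major
// storage; callers that need a scan-order guarantee renumber themselves.

static int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int>& parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export(name = ".cpp_label_components")]]
List cpp_label_components(IntegerMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(256);
  int next = 0;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0) { lab(r, c) = -1; continue; }
      // neighbors already visited in column-major order:
      // (r-1, c) same column; (r, c-1); diagonals (r-1, c-1), (r+1, c-1)
      int best = -1;
      int cand[4][2] = {{r - 1, c}, {r, c - 1}, {r - 1, c - 1}, {r + 1, c - 1}};
      int ncand = (connectivity == 8) ? 4 : 2;
      for (int k = 0; k < ncand; ++k) {
        int rr = cand[k][0], cc = cand[k][1];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int l = lab(rr, cc);
        if (l >= 0) {
          if (best < 0) best = l;
          else unite(parent, best, l);
        }
      }
      if (best < 0) {
        best = next++;
        parent.push_back(best);
      }
      lab(r, c) = best;
    }
  }

  // flatten and renumber to 1..n by order of root first appearance
  std::vector<int> newlab(next, 0);
  int n = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l < 0) { lab(r, c) = 0; continue; }
      int root = find_root(parent, l);
      if (newlab[root] == 0) newlab[root] = ++n;
      lab(r, c) = newlab[root];
    }

  IntegerVector areas(n);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) areas[lab(r, c) - 1]++;

  return List::create(_["labels"] = lab, _["n"] = n, _["areas"] = areas);
}
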