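#include <Rcpp.h>
using namespace Rcpp;

// 8-connected labeling of a binary mask (two-pass union-find).
// Returns an integer matrix with labels 1..K in first-encounter order.
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  auto find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int best = 0;
      // previously visited 8-neighbours under column-major scan order
      int ni[4] = {i - 1, i, i - 1, i + 1};
      int nj[4] = {j, j - 1, j - 1, j - 1};
      for (int k = 0; k < 4; ++k) {
        if (ni[k] < 0 || ni[k] >= nr || nj[k] < 0) continue;
        int l = lab(ni[k], nj[k]);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) {
        best = (int)parent.size();
        parent.push_back(best);
      }
      lab(i, j) = best;
    }
  }
  // second pass: flatten and renumber compactly in first-encounter order
  std::vector<int> newid(parent.size(), 0);
  int next = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) {
        int r = find(lab(i, j));
        if (newid[r] == 0) newid[r] = ++next;
        lab(i, j) = newid[r];
      }
  return lab;
}
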