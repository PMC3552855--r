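#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass union-find connected-component labelling for binary images.
// Labels are 1..k in first-encounter (column-major) order; background is 0.

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];  // path halving
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra < rb) parent[rb] = ra; else parent[ra] = rb;
}

// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const LogicalMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(256);
  parent.push_back(0);  // sentinel for background

  // first pass: provisional labels, scanning column-major (R layout)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int up   = (i > 0)           ? lab(i - 1, j) : 0;
      int left = (j > 0)           ? lab(i, j - 1) : 0;
      int ul = 0, dl = 0;
      if (connectivity == 8) {
        ul = (i > 0 && j > 0)      ? lab(i - 1, j - 1) : 0;
        dl = (i < nr - 1 && j > 0) ? lab(i + 1, j - 1) : 0;
      }
      int nb[4] = {up, left, ul, dl};
      int lmin = 0;
      for (int k = 0; k < 4; ++k)
        if (nb[k] > 0 && (lmin == 0 || nb[k] < lmin)) lmin = nb[k];
      if (lmin == 0) {
        int newlab = (int) parent.size();
        parent.push_back(newlab);
        lab(i, j) = newlab;
      } else {
        lab(i, j) = lmin;
        for (int k = 0; k < 4; ++k)
          if (nb[k] > 0 && nb[k] != lmin) uf_union(parent, nb[k], lmin);
      }
    }
  }

  // resolve and renumber consecutively
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) {
        int r = uf_find(parent, lab(i, j));
        if (remap[r] == 0) remap[r] = ++next;
        lab(i, j) = remap[r];
      }
  return lab;
}
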