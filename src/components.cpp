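#include <Rcpp.h>
using namespace Rcpp;

// Union-find over pixel indices; path halving keeps the trees flat.
static inline int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static inline void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

//' Label connected components of a logical matrix.
//'
//' @param mask logical matrix; NA is treated as FALSE.
//' @param connectivity 4 (edge-sharing neighbours) or 8 (edge- or
//'   corner-sharing neighbours).
//' @return integer matrix of the same shape: 0 for background pixels,
//'   components numbered 1..k in first-encounter (column-major) order.
//' @noRd
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int h = mask.nrow(), w = mask.ncol();
  const int n = h * w;
  std::vector<int> parent(n);

  // column-major index: i + j*h
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      const int idx = i + j * h;
      parent[idx] = idx;
      if (mask(i, j) != TRUE) continue;
      // union with already-visited neighbours (up, left; diagonals for 8)
      if (i > 0 && mask(i - 1, j) == TRUE) uf_union(parent, idx, idx - 1);
      if (j > 0 && mask(i, j - 1) == TRUE) uf_union(parent, idx, idx - h);
      if (connectivity == 8 && j > 0) {
        if (i > 0 && mask(i - 1, j - 1) == TRUE) uf_union(parent, idx, idx - h - 1);
        if (i < h - 1 && mask(i + 1, j - 1) == TRUE) uf_union(parent, idx, idx - h + 1);
      }
    }
  }

  IntegerMatrix labels(h, w);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (mask(i, j) != TRUE) continue;
      const int root = uf_find(parent, i + j * h);
      if (remap[root] == 0) remap[root] = ++next;
      labels(i, j) = remap[root];
    }
  }
  return labels;
}
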