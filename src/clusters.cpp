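#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Union-find with path halving.
static inline int find_root(std::vector<int>& p, int i) {
  while (p[i] != i) { p[i] = p[p[i]]; i = p[i]; }
  return i;
}

// Connected-component labels of the subgraph induced by `active`
// vertices. `edges` is E x 2 with 1-based vertex ids; labels are
// 1..n_components in order of first appearance, NA for inactive.
// [[Rcpp::export]]
IntegerVector cpp_label_components(int n, IntegerMatrix edges,
                                   LogicalVector active) {
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  const int E = edges.nrow();
  for (int e = 0; e < E; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    if (active[a] && active[b]) {
      int ra = find_root(parent, a), rb = find_root(parent, b);
      if (ra != rb) parent[ra] = rb;
    }
  }
  IntegerVector lab(n, NA_INTEGER);
  std::unordered_map<int, int> remap;
  int next = 1;
  for (int i = 0; i < n; ++i) {
    if (!active[i]) continue;
    int r = find_root(parent, i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = next; lab[i] = next; ++next; }
    else lab[i] = it->second;
  }
  return lab;
}

// Permutation null of the maximum supra-threshold cluster area.
// tmat: n_perm x n_vertex statistic matrix; direction 1 = greater
// (t > thresh), -1 = less (t < -thresh), 0 = two-sided (|t| > thresh);
// edges E x 2 (1-based); areas per-vertex surface area. Returns the
// largest cluster area per permutation (0 when no vertex is supra).
// [[Rcpp::export]]
NumericVector cpp_null_max_area(NumericMatrix tmat, double thresh,
                                int direction, IntegerMatrix edges,
                                NumericVector areas) {
  const int m = tmat.nrow(), n = tmat.ncol(), E = edges.nrow();
  NumericVector out(m);
  std::vector<int> parent(n);
  std::vector<double> carea(n);
  std::vector<char> act(n);
  for (int r = 0; r < m; ++r) {
    for (int i = 0; i < n; ++i) {
      double t = tmat(r, i);
      bool a = direction == 1 ? (t > thresh)
             : direction == -1 ? (t < -thresh)
             : (std::fabs(t) > thresh);
      act[i] = a;
      parent[i] = i;
      carea[i] = a ? areas[i] : 0.0;
    }
    for (int e = 0; e < E; ++e) {
      int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
      if (act[a] && act[b]) {
        int ra = find_root(parent, a), rb = find_root(parent, b);
        if (ra != rb) { parent[rb] = ra; carea[ra] += carea[rb]; }
      }
    }
    double mx = 0.0;
    for (int i = 0; i < n; ++i)
      if (act[i] && find_root(parent, i) == i && carea[i] > mx)
        mx = carea[i];
    out[r] = mx;
  }
  return out;
}
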