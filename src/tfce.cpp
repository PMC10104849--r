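#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Union-find with path halving and union by size.
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Threshold-free cluster enhancement on an arbitrary vertex graph.
//
// enhanced(v) = sum over h = dh, 2dh, ... <= stat(v) of
//              extent(v, h)^E * h^H * dh
// where extent(v, h) is the size of the connected component containing v
// among vertices with stat >= h. Computed by sweeping thresholds from the
// top and growing components incrementally with a union-find, so the cost
// is O(V * n_levels + E alpha(V)).
//
// stat: non-negative statistic per vertex; e1/e2: 0-based edge endpoints.
// [[Rcpp::export(name = ".tfce_enhance_cpp")]]
NumericVector tfce_enhance_cpp(NumericVector stat, IntegerVector e1,
                               IntegerVector e2, double E, double H,
                               double dh) {
  const int n = stat.size();
  const int m = e1.size();
  NumericVector enh(n);
  double hmax = 0.0;
  for (int i = 0; i < n; ++i) {
    if (stat[i] < 0) stop("tfce requires a non-negative statistic");
    if (stat[i] > hmax) hmax = stat[i];
  }
  if (hmax <= 0.0 || dh <= 0.0) return enh;
  const int nlev = (int)std::floor(hmax / dh + 1e-12);
  if (nlev < 1) return enh;

  // vertices sorted by stat descending; edges by min endpoint stat descending
  std::vector<int> vord(n);
  for (int i = 0; i < n; ++i) vord[i] = i;
  std::sort(vord.begin(), vord.end(),
            [&](int a, int b) { return stat[a] > stat[b]; });
  std::vector<int> eord(m);
  std::vector<double> emin(m);
  for (int i = 0; i < m; ++i) {
    eord[i] = i;
    emin[i] = std::min(stat[e1[i]], stat[e2[i]]);
  }
  std::sort(eord.begin(), eord.end(),
            [&](int a, int b) { return emin[a] > emin[b]; });

  std::vector<int> parent(n), csize(n, 1);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::vector<char> active(n, 0);

  int vi = 0, ei = 0;
  for (int lev = nlev; lev >= 1; --lev) {
    const double h = lev * dh;
    while (vi < n && stat[vord[vi]] >= h) {
      active[vord[vi]] = 1;
      ++vi;
    }
    while (ei < m && emin[eord[ei]] >= h) {
      int a = uf_find(parent, e1[eord[ei]]);
      int b = uf_find(parent, e2[eord[ei]]);
      if (a != b) {
        if (csize[a] < csize[b]) std::swap(a, b);
        parent[b] = a;
        csize[a] += csize[b];
      }
      ++ei;
    }
    const double hH = std::pow(h, H) * dh;
    for (int k = 0; k < vi; ++k) {
      const int v = vord[k];
      const int sz = csize[uf_find(parent, v)];
      enh[v] += std::pow((double)sz, E) * hH;
    }
  }
  return enh;
}
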