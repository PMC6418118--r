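#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Union-find over mask voxels, used by both the TFCE integrator and the
// connected-component labeller. Neighbours are supplied in CSR form
// (0-based voxel ids into the mask vector).

static int uf_find(std::vector<int>& parent, int v) {
  while (parent[v] != v) {
    parent[v] = parent[parent[v]];
    v = parent[v];
  }
  return v;
}

// TFCE over mask voxels: values (length nv), CSR neighbour lists.
// Integrates e(v,h)^E * h^H * dh over n_steps midpoint thresholds from 0 to
// max(values). Voxels <= 0 never contribute (the caller sign-flips for the
// negative direction).
// [[Rcpp::export]]
NumericVector tfce_kernel(NumericVector values, IntegerVector nbr,
                          IntegerVector ptr, double E, double H,
                          int n_steps) {
  const int nv = values.size();
  NumericVector out(nv);
  double hmax = 0.0;
  for (int i = 0; i < nv; ++i) if (values[i] > hmax) hmax = values[i];
  if (hmax <= 0.0 || n_steps < 1) return out;
  const double dh = hmax / n_steps;

  // voxel ids sorted by value descending
  std::vector<int> order(nv);
  for (int i = 0; i < nv; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return values[a] > values[b]; });

  std::vector<int> parent(nv), size(nv, 0);
  std::vector<char> active(nv, 0);
  for (int i = 0; i < nv; ++i) parent[i] = i;
  std::vector<int> active_list;
  active_list.reserve(nv);

  int next = 0; // pointer into `order`
  for (int s = n_steps; s >= 1; --s) {
    const double h = (s - 0.5) * dh;
    while (next < nv && values[order[next]] > h) {
      const int v = order[next++];
      active[v] = 1;
      size[v] = 1;
      active_list.push_back(v);
      for (int j = ptr[v]; j < ptr[v + 1]; ++j) {
        const int u = nbr[j];
        if (!active[u]) continue;
        const int ru = uf_find(parent, u), rv = uf_find(parent, v);
        if (ru != rv) {
          // union by size
          if (size[ru] < size[rv]) {
            parent[ru] = rv; size[rv] += size[ru];
          } else {
            parent[rv] = ru; size[ru] += size[rv];
          }
        }
      }
    }
    const double hh = std::pow(h, H) * dh;
    for (int v : active_list) {
      const int r = uf_find(parent, v);
      out[v] += std::pow((double)size[r], E) * hh;
    }
  }
  return out;
}

// Connected-component labels of a binary set over the mask graph.
// Returns 0 for voxels outside the set, 1..k component labels otherwise.
// [[Rcpp::export]]
IntegerVector label_components(LogicalVector in_set, IntegerVector nbr,
                               IntegerVector ptr) {
  const int nv = in_set.size();
  std::vector<int> parent(nv);
  for (int i = 0; i < nv; ++i) parent[i] = i;
  for (int v = 0; v < nv; ++v) {
    if (!in_set[v]) continue;
    for (int j = ptr[v]; j < ptr[v + 1]; ++j) {
      const int u = nbr[j];
      if (u < v || !in_set[u]) continue;
      const int ru = uf_find(parent, u), rv = uf_find(parent, v);
      if (ru != rv) parent[ru] = rv;
    }
  }
  IntegerVector labels(nv, 0);
  std::vector<int> remap(nv, 0);
  int k = 0;
  for (int v = 0; v < nv; ++v) {
    if (!in_set[v]) continue;
    const int r = uf_find(parent, v);
    if (remap[r] == 0) remap[r] = ++k;
    labels[v] = remap[r];
  }
  return labels;
}
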