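#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Rips persistence in dimensions 0 and 1 by boundary-matrix reduction
// over the two-element field. H0: union-find over the weight-sorted edge
// list (elder rule). H1: triangle columns (boundary = three edge rows,
// rows ordered by edge filtration position) reduced left to right; the
// pivot of a reduced triangle column is always a cycle-creating
// ("positive") edge, pairing bar [w(edge), w(triangle)]. Positive edges
// never killed are reported capped at max_filtration.

struct Edge { double w; int i, j; };
struct Tri  { double w; int i, j, k; };

static int uf_find(std::vector<int> &p, int x) {
  while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; }
  return x;
}

// [[Rcpp::export]]
NumericMatrix rips_persistence_cpp(NumericMatrix D, double max_filt,
                                   int max_dim) {
  int n = D.nrow();
  std::vector<Edge> edges;
  edges.reserve(n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (D(i, j) <= max_filt) edges.push_back({D(i, j), i, j});
  std::sort(edges.begin(), edges.end(), [](const Edge &a, const Edge &b) {
    if (a.w != b.w) return a.w < b.w;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  int m = (int)edges.size();

  std::vector<double> dim, birth, death, infin;
  std::vector<char> positive(m, 0);
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  int n_comp = n;
  for (int e = 0; e < m; ++e) {
    int a = uf_find(parent, edges[e].i), b = uf_find(parent, edges[e].j);
    if (a != b) {
      parent[a] = b;
      --n_comp;
      dim.push_back(0); birth.push_back(0.0);
      death.push_back(edges[e].w); infin.push_back(0);
    } else {
      positive[e] = 1;
    }
  }
  for (int c = 0; c < n_comp; ++c) {  // surviving component(s)
    dim.push_back(0); birth.push_back(0.0);
    death.push_back(max_filt); infin.push_back(1);
  }

  if (max_dim >= 1 && m > 0) {
    // edge index lookup
    std::vector<std::vector<int> > eidx(n, std::vector<int>(n, -1));
    for (int e = 0; e < m; ++e) {
      eidx[edges[e].i][edges[e].j] = e;
      eidx[edges[e].j][edges[e].i] = e;
    }
    std::vector<Tri> tris;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (eidx[i][j] < 0) continue;
        for (int k = j + 1; k < n; ++k) {
          if (eidx[i][k] < 0 || eidx[j][k] < 0) continue;
          double w = std::max(D(i, j), std::max(D(i, k), D(j, k)));
          if (w <= max_filt) tris.push_back({w, i, j, k});
        }
      }
    std::sort(tris.begin(), tris.end(), [](const Tri &a, const Tri &b) {
      if (a.w != b.w) return a.w < b.w;
      if (a.i != b.i) return a.i < b.i;
      if (a.j != b.j) return a.j < b.j;
      return a.k < b.k;
    });

    std::vector<int> pivot_of(m, -1);       // edge row -> reduced column id
    std::vector<std::vector<int> > cols;    // stored reduced columns
    std::vector<int> tmp, merged;
    for (size_t t = 0; t < tris.size(); ++t) {
      tmp.clear();
      tmp.push_back(eidx[tris[t].i][tris[t].j]);
      tmp.push_back(eidx[tris[t].i][tris[t].k]);
      tmp.push_back(eidx[tris[t].j][tris[t].k]);
      std::sort(tmp.begin(), tmp.end());
      while (!tmp.empty()) {
        int low = tmp.back();
        int other = pivot_of[low];
        if (other < 0) {
          // new pivot; the low of a 1-cycle is necessarily positive
          pivot_of[low] = (int)cols.size();
          cols.push_back(tmp);
          if (tris[t].w > edges[low].w) {
            dim.push_back(1); birth.push_back(edges[low].w);
            death.push_back(tris[t].w); infin.push_back(0);
          }
          break;
        }
        // symmetric difference with the stored column
        const std::vector<int> &oc = cols[other];
        merged.clear();
        std::set_symmetric_difference(tmp.begin(), tmp.end(),
                                      oc.begin(), oc.end(),
                                      std::back_inserter(merged));
        tmp.swap(merged);
      }
    }
    for (int e = 0; e < m; ++e) {
      if (positive[e] && pivot_of[e] < 0 && max_filt > edges[e].w) {
        dim.push_back(1); birth.push_back(edges[e].w);
        death.push_back(max_filt); infin.push_back(1);
      }
    }
  }

  NumericMatrix out(dim.size(), 4);
  for (size_t r = 0; r < dim.size(); ++r) {
    out(r, 0) = dim[r]; out(r, 1) = birth[r];
    out(r, 2) = death[r]; out(r, 3) = infin[r];
  }
  return out;
}
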