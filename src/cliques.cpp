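#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Recursive clique enumeration with candidate pruning. Candidates are
// restricted to higher-indexed neighbours so each clique is visited once.
static void extend(const std::vector<std::vector<int> > &nbr,
                   const std::vector<int> &cand, int size, int maxsize,
                   std::vector<double> &counts) {
  for (size_t a = 0; a < cand.size(); ++a) {
    int v = cand[a];
    counts[size]++;  // clique of (size + 1) vertices ending at v
    if (size + 1 < maxsize) {
      std::vector<int> next;
      const std::vector<int> &nv = nbr[v];
      // intersect cand[a+1..] with neighbours of v above v
      size_t i = a + 1, j = 0;
      while (i < cand.size() && j < nv.size()) {
        if (cand[i] == nv[j]) { next.push_back(cand[i]); ++i; ++j; }
        else if (cand[i] < nv[j]) ++i;
        else ++j;
      }
      if (!next.empty()) extend(nbr, next, size + 1, maxsize, counts);
    }
  }
}

// [[Rcpp::export]]
NumericVector count_cliques_cpp(LogicalMatrix adj, int K) {
  int n = adj.nrow();
  int maxsize = K + 1;
  std::vector<std::vector<int> > nbr(n);  // higher-indexed neighbours
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (adj(i, j)) nbr[i].push_back(j);
  std::vector<double> counts(maxsize, 0.0);
  counts[0] = n;
  if (maxsize > 1) {
    for (int v = 0; v < n; ++v)
      if (!nbr[v].empty()) extend(nbr, nbr[v], 1, maxsize, counts);
  }
  return NumericVector(counts.begin(), counts.end());
}
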