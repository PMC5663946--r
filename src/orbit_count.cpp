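// Per-node graphlet orbit counting via ESU enumeration.
//
// Enumerates every connected induced subgraph of size 2..5 exactly once
// (Wernicke's ESU: subsets grown from a root using only higher-numbered
// vertices from the exclusive neighborhood), classifies the labeled
// adjacency bit code through lookup tables built in R from the orbit
// catalog, and increments each member vertex's count at the orbit it
// occupies.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Esu {
  int n;
  std::vector<std::vector<int>> adj;     // sorted neighbor lists
  std::vector<const int*> lut;           // lut[k]: code*k + pos -> orbit
  NumericMatrix counts;                  // n x 73
  std::vector<char> in_sub, in_nbhd;
  std::vector<int> sub;
  int root;

  Esu(int n_) : n(n_), adj(n_), lut(6, nullptr),
                counts(n_, 73), in_sub(n_, 0), in_nbhd(n_, 0) {}

  bool adjacent(int a, int b) const {
    const std::vector<int>& v = adj[a];
    return std::binary_search(v.begin(), v.end(), b);
  }

  void record() {
    int k = (int)sub.size();
    std::vector<int> s(sub);
    std::sort(s.begin(), s.end());
    int code = 0, bit = 0;
    for (int i = 0; i < k; ++i)
      for (int j = i + 1; j < k; ++j) {
        if (adjacent(s[i], s[j])) code |= (1 << bit);
        ++bit;
      }
    const int* tab = lut[k];
    for (int i = 0; i < k; ++i) {
      int orb = tab[code * k + i];
      if (orb >= 0) counts(s[i], orb) += 1.0;
    }
  }

  void extend(std::vector<int>& ext) {
    if ((int)sub.size() >= 2) record();
    if ((int)sub.size() == 5 || ext.empty()) return;
    std::vector<int> local(ext);
    while (!local.empty()) {
      int w = local.back();
      local.pop_back();
      // exclusive neighborhood of w w.r.t. current subgraph
      std::vector<int> added;
      std::vector<int> ext2(local);
      for (int u : adj[w]) {
        if (u > root && !in_sub[u] && !in_nbhd[u]) {
          ext2.push_back(u);
          in_nbhd[u] = 1;
          added.push_back(u);
        }
      }
      sub.push_back(w);
      in_sub[w] = 1;
      extend(ext2);
      in_sub[w] = 0;
      sub.pop_back();
      for (int u : added) in_nbhd[u] = 0;
    }
  }

  void run() {
    for (int v = 0; v < n; ++v) {
      root = v;
      sub.assign(1, v);
      in_sub[v] = 1;
      std::vector<int> ext;
      std::vector<int> marked;
      for (int u : adj[v])
        if (u > v) {
          ext.push_back(u);
          in_nbhd[u] = 1;
          marked.push_back(u);
        }
      extend(ext);
      in_sub[v] = 0;
      for (int u : marked) in_nbhd[u] = 0;
    }
  }
};

} // namespace

// [[Rcpp::export]]
NumericMatrix orbit_counts_esu(List adj, List luts) {
  int n = adj.size();
  Esu esu(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj[i];
    esu.adj[i].assign(nb.begin(), nb.end());
  }
  for (int k = 2; k <= 5; ++k) {
    SEXP t = luts[k - 2];
    if (TYPEOF(t) != INTSXP) stop("orbit lookup tables must be integer");
    esu.lut[k] = INTEGER(t);
  }
  esu.run();
  return esu.counts;
}
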