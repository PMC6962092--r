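#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static inline long long enc_edge(int n, int u, int v) {
  return (long long)u * (n + 1) + v;
}

// Enumerate every weakly connected unordered node triple of a simple
// directed graph exactly once, returning sorted node indices (1-based)
// plus the 6-bit adjacency code of the (i<j<k)-ordered triple:
// bit1 i->j, bit2 j->i, bit4 i->k, bit8 k->i, bit16 j->k, bit32 k->j.
// [[Rcpp::export]]
IntegerMatrix cpp_connected_triads(int n, IntegerVector from, IntegerVector to) {
  int m = from.size();
  std::unordered_set<long long> dir;
  dir.reserve(m * 2);
  std::vector<std::vector<int>> nb(n + 1);
  {
    std::unordered_set<long long> und;
    und.reserve(m * 2);
    for (int i = 0; i < m; i++) {
      int u = from[i], v = to[i];
      if (u == v) continue;
      dir.insert(enc_edge(n, u, v));
      int a = std::min(u, v), b = std::max(u, v);
      if (und.insert(enc_edge(n, a, b)).second) {
        nb[a].push_back(b);
        nb[b].push_back(a);
      }
    }
  }
  std::unordered_set<long long> und2;
  und2.reserve(m * 2);
  for (int u = 1; u <= n; u++) {
    std::sort(nb[u].begin(), nb[u].end());
    for (int v : nb[u]) if (u < v) und2.insert(enc_edge(n, u, v));
  }
  std::vector<int> r1, r2, r3, rc;
  for (int b = 1; b <= n; b++) {
    const std::vector<int> &N = nb[b];
    int d = N.size();
    for (int ii = 0; ii < d; ii++) {
      for (int jj = ii + 1; jj < d; jj++) {
        int a = N[ii], c = N[jj]; // a < c
        bool tri = und2.count(enc_edge(n, a, c)) > 0;
        if (tri && b > a) continue; // triangles only from their min node
        int x1 = a, x2 = b, x3 = c;
        // sort ascending
        if (x1 > x2) std::swap(x1, x2);
        if (x2 > x3) std::swap(x2, x3);
        if (x1 > x2) std::swap(x1, x2);
        int code = 0;
        if (dir.count(enc_edge(n, x1, x2))) code |= 1;
        if (dir.count(enc_edge(n, x2, x1))) code |= 2;
        if (dir.count(enc_edge(n, x1, x3))) code |= 4;
        if (dir.count(enc_edge(n, x3, x1))) code |= 8;
        if (dir.count(enc_edge(n, x2, x3))) code |= 16;
        if (dir.count(enc_edge(n, x3, x2))) code |= 32;
        r1.push_back(x1); r2.push_back(x2); r3.push_back(x3); rc.push_back(code);
      }
    }
  }
  int k = r1.size();
  IntegerMatrix out(k, 4);
  for (int i = 0; i < k; i++) {
    out(i, 0) = r1[i]; out(i, 1) = r2[i]; out(i, 2) = r3[i]; out(i, 3) = rc[i];
  }
  colnames(out) = CharacterVector::create("n1", "n2", "n3", "code");
  return out;
}
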