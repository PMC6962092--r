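#include <Rcpp.h>
#include <unordered_set>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

static inline long long enc(int n, int u, int v) {
  return (long long)u * (n + 1) + v;
}

static inline int runif_int(int k) {
  int i = (int)(unif_rand() * k);
  return i >= k ? k - 1 : i;
}

// Degree-preserving edge swaps. Single (non-reciprocated) edges are swapped
// pairwise (a->b, c->d) => (a->d, c->b); mutual dyads are swapped only with
// other mutual dyads. Proposals creating self-loops, duplicate edges, or
// converting between single and mutual dyads are rejected. Edge slots keep
// their position so attribute rows stay attached to the travelling edge.
// Uses R's RNG (set.seed-controlled).
// [[Rcpp::export]]
List cpp_swap_edges(int n, IntegerVector from, IntegerVector to,
                    int n_swaps, double max_attempts) {
  RNGScope scope;
  int m = from.size();
  std::vector<int> ef(m), et(m);
  std::unordered_set<long long> S;
  S.reserve(m * 2);
  for (int i = 0; i < m; i++) {
    ef[i] = from[i]; et[i] = to[i];
    S.insert(enc(n, ef[i], et[i]));
  }
  // partition into singles and mutual dyads
  std::vector<int> singles;
  struct Dyad { int u, v, iuv, ivu; };
  std::vector<Dyad> mut;
  {
    std::unordered_map<long long, int> pos;
    pos.reserve(m * 2);
    for (int i = 0; i < m; i++) pos[enc(n, ef[i], et[i])] = i;
    std::vector<bool> used(m, false);
    for (int i = 0; i < m; i++) {
      if (used[i]) continue;
      auto it = pos.find(enc(n, et[i], ef[i]));
      if (it != pos.end() && it->second != i) {
        int j = it->second;
        used[i] = used[j] = true;
        mut.push_back({ef[i], et[i], i, j});
      } else {
        used[i] = true;
        singles.push_back(i);
      }
    }
  }
  int ns = singles.size(), nm = mut.size();
  int accepted = 0;
  double attempts = 0;
  bool can_single = ns >= 2, can_mut = nm >= 2;
  if (can_single || can_mut) {
    while (accepted < n_swaps && attempts < max_attempts) {
      attempts += 1;
      bool do_single;
      if (can_single && can_mut)
        do_single = unif_rand() * (ns + 2 * nm) < ns;
      else
        do_single = can_single;
      if (do_single) {
        int i = singles[runif_int(ns)];
        int j = singles[runif_int(ns)];
        if (i == j) continue;
        int a = ef[i], b = et[i], c = ef[j], d = et[j];
        if (a == c || b == d) continue;        // no-op swap
        if (a == d || c == b) continue;        // would create self-loop
        if (S.count(enc(n, a, d)) || S.count(enc(n, c, b))) continue;
        if (S.count(enc(n, d, a)) || S.count(enc(n, b, c))) continue; // would create mutual
        S.erase(enc(n, a, b)); S.erase(enc(n, c, d));
        S.insert(enc(n, a, d)); S.insert(enc(n, c, b));
        et[i] = d; et[j] = b;
        accepted++;
      } else {
        int p = runif_int(nm), q = runif_int(nm);
        if (p == q) continue;
        Dyad &P = mut[p], &Q = mut[q];
        int u1 = P.u, v1 = P.v, u2 = Q.u, v2 = Q.v;
        if (unif_rand() < 0.5) { std::swap(u2, v2); std::swap(Q.iuv, Q.ivu); Q.u = u2; Q.v = v2; }
        // new dyads {u1, v2} and {u2, v1}
        if (u1 == u2 || u1 == v2 || v1 == u2 || v1 == v2) continue;
        if (S.count(enc(n, u1, v2)) || S.count(enc(n, v2, u1)) ||
            S.count(enc(n, u2, v1)) || S.count(enc(n, v1, u2))) continue;
        S.erase(enc(n, u1, v1)); S.erase(enc(n, v1, u1));
        S.erase(enc(n, u2, v2)); S.erase(enc(n, v2, u2));
        S.insert(enc(n, u1, v2)); S.insert(enc(n, v2, u1));
        S.insert(enc(n, u2, v1)); S.insert(enc(n, v1, u2));
        ef[P.iuv] = u1; et[P.iuv] = v2;   // u1->v2 carries u1->v1
        ef[Q.ivu] = v2; et[Q.ivu] = u1;   // v2->u1 carries v2->u2
        ef[Q.iuv] = u2; et[Q.iuv] = v1;   // u2->v1 carries u2->v2
        ef[P.ivu] = v1; et[P.ivu] = u2;   // v1->u2 carries v1->u1
        int old_p_ivu = P.ivu;
        P.v = v2; P.ivu = Q.ivu;
        Q.v = v1; Q.ivu = old_p_ivu;
        accepted++;
      }
    }
  }
  return List::create(_["from"] = IntegerVector(ef.begin(), ef.end()),
                      _["to"] = IntegerVector(et.begin(), et.end()),
                      _["accepted"] = accepted,
                      _["attempts"] = attempts);
}
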