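#include <Rcpp.h>
#include <unordered_set>
#include <random>

// Degree-preserving rewiring by double-edge swaps. Two edges (a,b), (c,d)
// are replaced by (a,d), (c,b) (or (a,c), (b,d)); a swap is rejected when it
// would create a self-loop or a multi-edge, so the degree sequence is
// preserved exactly. Runs until `target_swaps` swaps are accepted or
// `max_tries` proposals have been made.
//
// `edges` is an |E| x 2 integer matrix of 0-based node ids.
// Returns the rewired edge matrix with attribute "accepted".
// [[Rcpp::export(name = ".rewire_edges_cpp")]]
Rcpp::IntegerMatrix rewire_edges_cpp(Rcpp::IntegerMatrix edges, int n_nodes,
                                     int target_swaps, int max_tries,
                                     int seed) {
  const int m = edges.nrow();
  std::vector<int> a(m), b(m);
  std::unordered_set<long long> present;
  present.reserve(m * 2);
  auto key = [n_nodes](int x, int y) {
    if (x > y) std::swap(x, y);
    return (long long)x * (long long)n_nodes + (long long)y;
  };
  for (int i = 0; i < m; ++i) {
    a[i] = edges(i, 0);
    b[i] = edges(i, 1);
    present.insert(key(a[i], b[i]));
  }
  std::mt19937 rng((unsigned int)seed);
  std::uniform_int_distribution<int> pick(0, m - 1);
  std::uniform_int_distribution<int> coin(0, 1);
  int accepted = 0, tries = 0;
  while (accepted < target_swaps && tries < max_tries && m >= 2) {
    ++tries;
    int i = pick(rng), j = pick(rng);
    if (i == j) continue;
    int ai = a[i], bi = b[i], aj = a[j], bj = b[j];
    // swap orientation of edge j half the time so both pairings are reachable
    if (coin(rng)) std::swap(aj, bj);
    // proposed edges: (ai, bj) and (aj, bi)
    if (ai == bj || aj == bi) continue;                  // self-loop
    long long k1 = key(ai, bj), k2 = key(aj, bi);
    if (k1 == k2) continue;
    if (present.count(k1) || present.count(k2)) continue; // multi-edge
    present.erase(key(ai, bi));
    present.erase(key(aj, bj));
    present.insert(k1);
    present.insert(k2);
    a[i] = ai; b[i] = bj;
    a[j] = aj; b[j] = bi;
    ++accepted;
  }
  Rcpp::IntegerMatrix out(m, 2);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = a[i];
    out(i, 1) = b[i];
  }
  out.attr("accepted") = accepted;
  return out;
}
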