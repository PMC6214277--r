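#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Edge-switching randomization preserving every node's in-/out-degree and
// the number of mutual (bi-directional) dyads. Uni-directional links are
// swapped only with uni-directional links and mutual dyads only with
// mutual dyads; a swap is rejected if it would create a self-loop, a
// duplicate link, or promote/demote a dyad between the classes. Uses R's
// RNG so draws are reproducible under set.seed().
//
// [[Rcpp::export]]
List rewire_switching(IntegerMatrix adj, int attempts) {
  int n = adj.nrow();
  std::vector<char> A(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      A[i * n + j] = (char)(adj(i, j) != 0);

  std::vector<std::pair<int, int> > singles;  // a -> b, no b -> a
  std::vector<std::pair<int, int> > mutuals;  // {a, b}, a < b, both ways
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j || !A[i * n + j]) continue;
      if (A[j * n + i]) {
        if (i < j) mutuals.push_back(std::make_pair(i, j));
      } else {
        singles.push_back(std::make_pair(i, j));
      }
    }
  }

  int ns = (int)singles.size();
  int nm = (int)mutuals.size();
  int n_swaps = 0;

  for (int it = 0; it < attempts; ++it) {
    if (ns + nm == 0) break;
    // pick the link class proportional to its dyad count
    bool do_single = (unif_rand() * (ns + nm)) < ns;
    if (do_single) {
      if (ns < 2) continue;
      int e1 = (int)(unif_rand() * ns);
      int e2 = (int)(unif_rand() * ns);
      if (e1 == e2) continue;
      int a = singles[e1].first, b = singles[e1].second;
      int c = singles[e2].first, d = singles[e2].second;
      // propose a -> d and c -> b
      if (a == d || c == b) continue;            // self-loop
      if (A[a * n + d] || A[c * n + b]) continue; // duplicate link
      if (A[d * n + a] || A[b * n + c]) continue; // would create mutual dyad
      A[a * n + b] = 0; A[c * n + d] = 0;
      A[a * n + d] = 1; A[c * n + b] = 1;
      singles[e1].second = d;
      singles[e2].second = b;
      ++n_swaps;
    } else {
      if (nm < 2) continue;
      int e1 = (int)(unif_rand() * nm);
      int e2 = (int)(unif_rand() * nm);
      if (e1 == e2) continue;
      int a = mutuals[e1].first, b = mutuals[e1].second;
      int c = mutuals[e2].first, d = mutuals[e2].second;
      if (a == c || a == d || b == c || b == d) continue;
      // two possible re-pairings; choose one at random
      int p, q, r, s;
      if (unif_rand() < 0.5) { p = a; q = d; r = c; s = b; }
      else                   { p = a; q = c; r = b; s = d; }
      if (A[p * n + q] || A[q * n + p] || A[r * n + s] || A[s * n + r])
        continue;  // any existing link blocks the new dyads
      A[a * n + b] = 0; A[b * n + a] = 0;
      A[c * n + d] = 0; A[d * n + c] = 0;
      A[p * n + q] = 1; A[q * n + p] = 1;
      A[r * n + s] = 1; A[s * n + r] = 1;
      mutuals[e1] = std::make_pair(std::min(p, q), std::max(p, q));
      mutuals[e2] = std::make_pair(std::min(r, s), std::max(r, s));
      ++n_swaps;
    }
  }

  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      out(i, j) = A[i * n + j];
  out.attr("dimnames") = adj.attr("dimnames");
  return List::create(_["adjacency"] = out, _["n_swaps"] = n_swaps);
}
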