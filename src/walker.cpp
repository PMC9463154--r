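#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include "rng.h"

using namespace Rcpp;

// Weighted random walks over a graph in CSR form.
//
// indptr (length n+1), indices (0-based neighbour ids) and weights describe
// the out-neighbourhood of every node; per-node weights are normalized to
// transition probabilities (cumulative sums + binary search). With
// p = q = 1 the walk is first-order Markov; otherwise a second-order
// node2vec walker applies the return (1/p) and in-out (1/q) factors using
// binary search on the sorted neighbour lists.
//
// One walk of length `walk_length` starts at every non-isolated node per
// repetition; the node order is reshuffled each repetition. All randomness
// comes from `seed`.
// [[Rcpp::export(name = ".walk_corpus_cpp")]]
IntegerMatrix walk_corpus_cpp(IntegerVector indptr, IntegerVector indices,
                              NumericVector weights, int n_nodes,
                              int walks_per_node, int walk_length,
                              double p, double q, double seed) {
  const bool first_order = (p == 1.0 && q == 1.0);
  XRng rng(static_cast<uint64_t>(seed));

  // cumulative weights per node for O(log d) sampling
  std::vector<double> cumw(weights.size());
  std::vector<double> totw(n_nodes, 0.0);
  for (int v = 0; v < n_nodes; ++v) {
    double acc = 0.0;
    for (int k = indptr[v]; k < indptr[v + 1]; ++k) {
      acc += weights[k];
      cumw[k] = acc;
    }
    totw[v] = acc;
  }

  std::vector<int> anchors;
  anchors.reserve(n_nodes);
  for (int v = 0; v < n_nodes; ++v)
    if (indptr[v + 1] > indptr[v] && totw[v] > 0) anchors.push_back(v);

  const int n_anchor = static_cast<int>(anchors.size());
  IntegerMatrix walks(n_anchor * walks_per_node, walk_length);

  auto sample_nb = [&](int v) {
    const int lo = indptr[v], hi = indptr[v + 1];
    const double u = rng.unif() * totw[v];
    const double* first = &cumw[lo];
    const double* it = std::upper_bound(first, first + (hi - lo), u);
    int k = lo + static_cast<int>(it - first);
    if (k >= hi) k = hi - 1;
    return k;
  };
  auto is_neighbor = [&](int v, int x) {
    const int lo = indptr[v], hi = indptr[v + 1];
    return std::binary_search(&indices[lo], &indices[hi], x);
  };

  std::vector<int> order(anchors);
  int row = 0;
  for (int rep = 0; rep < walks_per_node; ++rep) {
    // Fisher-Yates reshuffle per repetition
    for (int i = n_anchor - 1; i > 0; --i) {
      int j = static_cast<int>(rng.bounded(i + 1));
      std::swap(order[i], order[j]);
    }
    for (int a = 0; a < n_anchor; ++a, ++row) {
      int cur = order[a];
      int prev = -1;
      walks(row, 0) = cur + 1;  // 1-based for R
      for (int step = 1; step < walk_length; ++step) {
        int k;
        if (first_order || prev < 0) {
          k = sample_nb(cur);
        } else {
          // second-order: weight * (back ? 1/p : neighbor(prev) ? 1 : 1/q)
          const int lo = indptr[cur], hi = indptr[cur + 1];
          double tot = 0.0;
          thread_local std::vector<double> buf;
          buf.resize(hi - lo);
          for (int t = lo; t < hi; ++t) {
            const int nb = indices[t];
            double f = (nb == prev) ? 1.0 / p
                     : (is_neighbor(prev, nb) ? 1.0 : 1.0 / q);
            tot += weights[t] * f;
            buf[t - lo] = tot;
          }
          const double u = rng.unif() * tot;
          int off = static_cast<int>(std::upper_bound(buf.begin(), buf.end(), u)
                                     - buf.begin());
          if (off >= hi - lo) off = hi - lo - 1;
          k = lo + off;
        }
        prev = cur;
        cur = indices[k];
        walks(row, step) = cur + 1;
      }
    }
  }
  return walks;
}
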