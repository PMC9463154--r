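#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// Skip-gram with negative sampling (SGNS) over a corpus of fixed-length
// walks, in the style of the reference word2vec C implementation:
// precomputed sigmoid table, unigram^0.75 negative-sampling table, dynamic
// window (uniform shrink per centre token) and linear learning-rate decay.
// Single-threaded and bit-reproducible for a given seed.
//
// walks: matrix of 1-based vocabulary indices (one walk per row).
// counts: token frequency per vocabulary entry (for the negative table).
// Returns the input (centre) vectors, vocab_size x dim.
// [[Rcpp::export(name = ".sgns_train_cpp")]]
NumericMatrix sgns_train_cpp(IntegerMatrix walks, IntegerVector counts,
                             int dim, int window, int negative, int epochs,
                             double alpha, double min_alpha, double seed) {
  const int vocab = counts.size();
  const int n_walk = walks.nrow();
  const int wl = walks.ncol();
  XRng rng(static_cast<uint64_t>(seed));

  // sigmoid lookup, as in word2vec (MAX_EXP = 6)
  const int EXP_TABLE_SIZE = 1000;
  const double MAX_EXP = 6.0;
  std::vector<double> expTable(EXP_TABLE_SIZE);
  for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
    double e = std::exp((i / (double)EXP_TABLE_SIZE * 2.0 - 1.0) * MAX_EXP);
    expTable[i] = e / (e + 1.0);
  }

  // unigram^0.75 negative-sampling table
  const int TABLE_SIZE = 1 << 20;
  std::vector<int> negTable(TABLE_SIZE);
  {
    double total = 0.0;
    for (int v = 0; v < vocab; ++v) total += std::pow((double)counts[v], 0.75);
    int v = 0;
    double cum = std::pow((double)counts[0], 0.75) / total;
    for (int i = 0; i < TABLE_SIZE; ++i) {
      negTable[i] = v;
      if ((i + 1.0) / TABLE_SIZE > cum && v < vocab - 1) {
        ++v;
        cum += std::pow((double)counts[v], 0.75) / total;
      }
    }
  }

  // single-precision weights, as in the reference implementation
  std::vector<float> syn0((size_t)vocab * dim);
  std::vector<float> syn1((size_t)vocab * dim, 0.0f);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (float)((rng.unif() - 0.5) / dim);

  const double total_tokens = (double)n_walk * wl * epochs;
  double processed = 0.0;
  std::vector<float> grad(dim);
  std::vector<int> sen(wl);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_walk; ++s) {
      // contiguous copy of the walk: the corpus matrix is column-major
      // and striding through it inside the training loop thrashes cache
      for (int pos = 0; pos < wl; ++pos) sen[pos] = walks(s, pos) - 1;
      for (int pos = 0; pos < wl; ++pos, ++processed) {
        double lr = alpha * (1.0 - processed / total_tokens);
        if (lr < min_alpha) lr = min_alpha;
        const float flr = (float)lr;
        const int center = sen[pos];
        const int b = (int)rng.bounded(window);  // dynamic window shrink
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          const int cpos = pos + off;
          if (cpos < 0 || cpos >= wl) continue;
          const int context = sen[cpos];
          float* v_in = &syn0[(size_t)context * dim];
          std::fill(grad.begin(), grad.end(), 0.0f);
          for (int d = 0; d < negative + 1; ++d) {
            int target, label;
            if (d == 0) { target = center; label = 1; }
            else {
              target = negTable[rng.bounded(TABLE_SIZE)];
              if (target == center) continue;
              label = 0;
            }
            float* v_out = &syn1[(size_t)target * dim];
            float f = 0.0f;
            for (int k = 0; k < dim; ++k) f += v_in[k] * v_out[k];
            float g;
            if (f > MAX_EXP) g = (label - 1) * flr;
            else if (f < -MAX_EXP) g = (float)label * flr;
            else {
              int ei = (int)((f + MAX_EXP) * (EXP_TABLE_SIZE / MAX_EXP / 2.0));
              g = ((float)label - (float)expTable[ei]) * flr;
            }
            for (int k = 0; k < dim; ++k) grad[k] += g * v_out[k];
            for (int k = 0; k < dim; ++k) v_out[k] += g * v_in[k];
          }
          for (int k = 0; k < dim; ++k) v_in[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(vocab, dim);
  for (int v = 0; v < vocab; ++v)
    for (int k = 0; k < dim; ++k) out(v, k) = syn0[(size_t)v * dim + k];
  return out;
}
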