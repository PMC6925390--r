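#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Continuous bag-of-words word2vec with negative sampling.
// Single-threaded with a private xorshift RNG so training is bit-reproducible
// for a given seed regardless of R's RNG state.

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 88172645463325252ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// sentences: list of integer vectors with 0-based token ids (all < vocab).
// counts: token frequencies (length vocab) for the negative-sampling table.
// [[Rcpp::export(name = ".cbow_train")]]
NumericMatrix cbow_train(List sentences, IntegerVector counts, int dim,
                         int window, int negative, int epochs,
                         double alpha, double min_alpha, int seed) {
  const int V = counts.size();
  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  // unigram^0.75 table
  const int table_size = 1 << 17;
  std::vector<int> table(table_size);
  {
    double total = 0.0;
    for (int i = 0; i < V; ++i) total += std::pow((double)counts[i], 0.75);
    double cum = std::pow((double)counts[0], 0.75) / total;
    int w = 0;
    for (int i = 0; i < table_size; ++i) {
      table[i] = w;
      if ((double)(i + 1) / table_size > cum && w < V - 1) {
        ++w;
        cum += std::pow((double)counts[w], 0.75) / total;
      }
    }
  }

  std::vector<double> syn0((size_t)V * dim), syn1((size_t)V * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  long long total_words = 0;
  const int S = sentences.size();
  std::vector<std::vector<int>> sent(S);
  for (int s = 0; s < S; ++s) {
    IntegerVector v = sentences[s];
    sent[s].assign(v.begin(), v.end());
    total_words += v.size();
  }
  const long long train_total = total_words * (long long)epochs;
  long long seen = 0;

  std::vector<double> h(dim), neu1e(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < S; ++s) {
      const std::vector<int>& sen = sent[s];
      const int n = (int)sen.size();
      for (int pos = 0; pos < n; ++pos, ++seen) {
        double lr = alpha * (1.0 - (double)seen / (double)(train_total + 1));
        if (lr < min_alpha) lr = min_alpha;
        int lo = pos - window; if (lo < 0) lo = 0;
        int hi = pos + window; if (hi > n - 1) hi = n - 1;
        int cw = hi - lo;       // context count (excluding centre)
        if (cw <= 0) continue;
        std::fill(h.begin(), h.end(), 0.0);
        for (int j = lo; j <= hi; ++j) {
          if (j == pos) continue;
          const double* v0 = &syn0[(size_t)sen[j] * dim];
          for (int d = 0; d < dim; ++d) h[d] += v0[d];
        }
        for (int d = 0; d < dim; ++d) h[d] /= cw;
        std::fill(neu1e.begin(), neu1e.end(), 0.0);
        for (int k = 0; k <= negative; ++k) {
          int target; double label;
          if (k == 0) { target = sen[pos]; label = 1.0; }
          else {
            target = table[rng.next() % table_size];
            if (target == sen[pos]) continue;
            label = 0.0;
          }
          double* v1 = &syn1[(size_t)target * dim];
          double f = 0.0;
          for (int d = 0; d < dim; ++d) f += h[d] * v1[d];
          double g = (label - sigmoid(f)) * lr;
          for (int d = 0; d < dim; ++d) { neu1e[d] += g * v1[d]; v1[d] += g * h[d]; }
        }
        for (int j = lo; j <= hi; ++j) {
          if (j == pos) continue;
          double* v0 = &syn0[(size_t)sen[j] * dim];
          for (int d = 0; d < dim; ++d) v0[d] += neu1e[d];
        }
      }
    }
  }

  NumericMatrix out(V, dim);
  for (int i = 0; i < V; ++i)
    for (int d = 0; d < dim; ++d)
      out(i, d) = syn0[(size_t)i * dim + d];
  return out;
}
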