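#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Deterministic 64-bit xorshift RNG so training is bitwise reproducible for a
// fixed seed, independent of R's RNG state.
static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s;
}

static inline double runif01(uint64_t &s) {
  return (double)(xorshift64(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoidd(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over integer-coded sentences (0-based ids).
// Single-threaded by design; the unigram^(3/4) noise distribution is sampled
// by binary search over its cumulative mass.
// [[Rcpp::export]]
NumericMatrix sgns_train(List sentences, int vocab_size, NumericVector counts,
                         int dim, int window, int negative, int epochs,
                         double alpha, double min_alpha, double sample,
                         double seed) {
  uint64_t rng = (uint64_t)seed * 2654435761u + 88172645463325252ull;
  // warm up
  for (int i = 0; i < 8; ++i) xorshift64(rng);

  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (runif01(rng) - 0.5) / dim;

  std::vector<double> cum(vocab_size);
  double tot = 0.0;
  for (int i = 0; i < vocab_size; ++i) {
    tot += std::pow(counts[i], 0.75);
    cum[i] = tot;
  }

  double total_count = 0.0;
  for (int i = 0; i < vocab_size; ++i) total_count += counts[i];

  long long total_words = 0;
  int n_sent = sentences.size();
  for (int s = 0; s < n_sent; ++s)
    total_words += ((IntegerVector)sentences[s]).size();
  total_words *= epochs;
  if (total_words < 1) total_words = 1;

  std::vector<double> neu1e(dim);
  std::vector<int> sen;
  long long processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      if ((s & 1023) == 0) Rcpp::checkUserInterrupt();
      IntegerVector sent = sentences[s];
      sen.clear();
      for (int t = 0; t < sent.size(); ++t) {
        ++processed;
        int w = sent[t];
        if (sample > 0) {
          double f = counts[w] / total_count;
          double keep = (std::sqrt(f / sample) + 1.0) * (sample / f);
          if (keep < runif01(rng)) continue;
        }
        sen.push_back(w);
      }
      int len = (int)sen.size();
      double a = alpha * (1.0 - (double)processed / (double)(total_words + 1));
      if (a < min_alpha) a = min_alpha;
      for (int pos = 0; pos < len; ++pos) {
        int word = sen[pos];
        int b = (int)(xorshift64(rng) % (uint64_t)window);
        for (int off = b; off < window * 2 + 1 - b; ++off) {
          if (off == window) continue;
          int c = pos - window + off;
          if (c < 0 || c >= len) continue;
          int last_word = sen[c];
          size_t l1 = (size_t)last_word * dim;
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = word;
              label = 1.0;
            } else {
              double r = runif01(rng) * tot;
              target = (int)(std::lower_bound(cum.begin(), cum.end(), r) -
                             cum.begin());
              if (target >= vocab_size) target = vocab_size - 1;
              if (target == word) continue;
              label = 0.0;
            }
            size_t l2 = (size_t)target * dim;
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += syn0[l1 + k] * syn1[l2 + k];
            double g = (label - sigmoidd(f)) * a;
            for (int k = 0; k < dim; ++k) neu1e[k] += g * syn1[l2 + k];
            for (int k = 0; k < dim; ++k) syn1[l2 + k] += g * syn0[l1 + k];
          }
          for (int k = 0; k < dim; ++k) syn0[l1 + k] += neu1e[k];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int i = 0; i < vocab_size; ++i)
    for (int k = 0; k < dim; ++k) out(i, k) = syn0[(size_t)i * dim + k];
  return out;
}
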