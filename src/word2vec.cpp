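// Single-threaded word2vec (skip-gram / CBOW with negative sampling).
// Deterministic: all randomness flows from one 64-bit LCG seeded by the
// caller, and updates run in corpus order on one thread.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

struct Lcg {
  uint64_t state;
  explicit Lcg(uint64_t seed) : state(seed) {}
  uint64_t next() {
    state = state * 25214903917ULL + 11ULL;
    return state;
  }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// sentences: list of integer vectors with 0-based vocabulary indices
// counts: vocabulary frequencies (for the unigram^0.75 sampling table)
// [[Rcpp::export(name = ".w2v_train")]]
NumericMatrix w2v_train(List sentences, int vocab_size, NumericVector counts,
                        int dim, int window, bool skipgram, int negative,
                        int epochs, double alpha0, int seed) {
  const int table_size = 100000;
  std::vector<int> table(table_size);
  {
    double z = 0.0;
    for (int i = 0; i < vocab_size; ++i) z += std::pow(counts[i], 0.75);
    double cum = std::pow(counts[0], 0.75) / z;
    int i = 0;
    for (int a = 0; a < table_size; ++a) {
      table[a] = i;
      if ((double)a / table_size > cum && i < vocab_size - 1) {
        ++i;
        cum += std::pow(counts[i], 0.75) / z;
      }
    }
  }

  Lcg rng((uint64_t)seed * 2654435761ULL + 1ULL);
  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = (((rng.next() >> 16) % 65536) / 65536.0 - 0.5) / dim;
  }

  long long total_words = 0;
  const int n_sent = sentences.size();
  std::vector<std::vector<int>> sents(n_sent);
  for (int s = 0; s < n_sent; ++s) {
    IntegerVector iv = sentences[s];
    sents[s].assign(iv.begin(), iv.end());
    total_words += iv.size();
  }
  if (total_words == 0) stop("Corpus has no in-vocabulary words.");

  std::vector<double> neu1(dim), neu1e(dim);
  long long processed = 0;
  const double train_total = (double)total_words * epochs + 1.0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      const std::vector<int>& sen = sents[s];
      const int len = (int)sen.size();
      for (int pos = 0; pos < len; ++pos) {
        double alpha = alpha0 * (1.0 - processed / train_total);
        if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;
        ++processed;
        const int word = sen[pos];
        const int b = (int)(rng.next() % (uint64_t)window);

        if (skipgram) {
          for (int a = b; a < window * 2 + 1 - b; ++a) {
            if (a == window) continue;
            const int c = pos - window + a;
            if (c < 0 || c >= len) continue;
            const int ctx = sen[c];
            double* l1 = &syn0[(size_t)ctx * dim];
            std::fill(neu1e.begin(), neu1e.end(), 0.0);
            for (int d = 0; d <= negative; ++d) {
              int target;
              double label;
              if (d == 0) {
                target = word;
                label = 1.0;
              } else {
                target = table[(rng.next() >> 16) % table_size];
                if (target == word) continue;
                label = 0.0;
              }
              double* l2 = &syn1[(size_t)target * dim];
              double f = 0.0;
              for (int k = 0; k < dim; ++k) f += l1[k] * l2[k];
              const double g = (label - sigmoid(f)) * alpha;
              for (int k = 0; k < dim; ++k) neu1e[k] += g * l2[k];
              for (int k = 0; k < dim; ++k) l2[k] += g * l1[k];
            }
            for (int k = 0; k < dim; ++k) l1[k] += neu1e[k];
          }
        } else {  // CBOW: mean of context predicts the centre word
          std::fill(neu1.begin(), neu1.end(), 0.0);
          int cw = 0;
          for (int a = b; a < window * 2 + 1 - b; ++a) {
            if (a == window) continue;
            const int c = pos - window + a;
            if (c < 0 || c >= len) continue;
            const double* l1 = &syn0[(size_t)sen[c] * dim];
            for (int k = 0; k < dim; ++k) neu1[k] += l1[k];
            ++cw;
          }
          if (cw == 0) continue;
          for (int k = 0; k < dim; ++k) neu1[k] /= cw;
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = word;
              label = 1.0;
            } else {
              target = table[(rng.next() >> 16) % table_size];
              if (target == word) continue;
              label = 0.0;
            }
            double* l2 = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += neu1[k] * l2[k];
            const double g = (label - sigmoid(f)) * alpha;
            for (int k = 0; k < dim; ++k) neu1e[k] += g * l2[k];
            for (int k = 0; k < dim; ++k) l2[k] += g * neu1[k];
          }
          for (int a = b; a < window * 2 + 1 - b; ++a) {
            if (a == window) continue;
            const int c = pos - window + a;
            if (c < 0 || c >= len) continue;
            double* l1 = &syn0[(size_t)sen[c] * dim];
            for (int k = 0; k < dim; ++k) l1[k] += neu1e[k];
          }
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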