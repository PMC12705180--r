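#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Minimal xorshift-based RNG so sampling is bit-reproducible across
// platforms independently of R's RNG state.
struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform double in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int unif_int(int n) { return (int)(unif() * n); }
};

// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// doc, word: token stream, 0-based document and vocabulary indices
// n_docs, vocab_size: dimensions; n_topics: K
// alpha, beta: symmetric Dirichlet hyperparameters
// n_sweeps: full passes of the sampler over the token stream
// seed: RNG seed
//
// Returns phi (K x V), theta (n_docs x K), both posterior-mean estimates
// from the final state.
// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector doc, IntegerVector word,
                   int n_docs, int vocab_size, int n_topics,
                   double alpha, double beta, int n_sweeps, double seed) {
  const int n_tok = doc.size();
  const int K = n_topics;
  const int V = vocab_size;

  SplitMix64 rng((uint64_t)seed + 0x5DEECE66DULL);

  std::vector<int> z(n_tok);
  std::vector<int> ndk((size_t)n_docs * K, 0);
  std::vector<int> nkw((size_t)K * V, 0);
  std::vector<int> nk(K, 0);
  std::vector<int> nd(n_docs, 0);

  for (int i = 0; i < n_tok; ++i) {
    int k = rng.unif_int(K);
    z[i] = k;
    ndk[(size_t)doc[i] * K + k]++;
    nkw[(size_t)k * V + word[i]]++;
    nk[k]++;
    nd[doc[i]]++;
  }

  std::vector<double> p(K);
  const double vbeta = V * beta;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int i = 0; i < n_tok; ++i) {
      const int d = doc[i];
      const int w = word[i];
      int k = z[i];
      ndk[(size_t)d * K + k]--;
      nkw[(size_t)k * V + w]--;
      nk[k]--;

      double total = 0.0;
      for (int t = 0; t < K; ++t) {
        double pt = (ndk[(size_t)d * K + t] + alpha) *
                    (nkw[(size_t)t * V + w] + beta) / (nk[t] + vbeta);
        total += pt;
        p[t] = total;
      }
      const double u = rng.unif() * total;
      int knew = 0;
      while (knew < K - 1 && p[knew] <= u) ++knew;

      z[i] = knew;
      ndk[(size_t)d * K + knew]++;
      nkw[(size_t)knew * V + w]++;
      nk[knew]++;
    }
    if (sweep % 8 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix phi(K, V);
  for (int k = 0; k < K; ++k) {
    const double denom = nk[k] + vbeta;
    for (int w = 0; w < V; ++w) {
      phi(k, w) = (nkw[(size_t)k * V + w] + beta) / denom;
    }
  }
  NumericMatrix theta(n_docs, K);
  for (int d = 0; d < n_docs; ++d) {
    const double denom = nd[d] + K * alpha;
    for (int k = 0; k < K; ++k) {
      theta(d, k) = (ndk[(size_t)d * K + k] + alpha) / denom;
    }
  }
  return List::create(Named("phi") = phi, Named("theta") = theta);
}
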