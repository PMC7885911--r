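#include <Rcpp.h>
#include <random>
#include <vector>

using namespace Rcpp;

// Collapsed Gibbs sampler for Latent Dirichlet Allocation.
//
// docs: list of integer vectors of 0-based vocabulary ids (one per document,
// zero-length documents must be removed by the caller). Returns the
// document-topic matrix theta (k x M, columns sum to 1, smoothed by alpha)
// and the topic-word matrix beta (k x V, rows sum to 1, smoothed by eta)
// estimated from the final sampler state. The RNG is a private mt19937
// seeded from `seed`, so results are reproducible and independent of R's
// RNG state.
// [[Rcpp::export]]
List lda_gibbs_cpp(List docs, int k, int V, double alpha, double eta,
                   int iterations, int seed) {
  const int M = docs.size();
  std::vector<std::vector<int>> w(M);
  for (int m = 0; m < M; ++m) {
    IntegerVector d = docs[m];
    w[m].assign(d.begin(), d.end());
  }

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<std::vector<int>> z(M);
  std::vector<int> n_dk(static_cast<size_t>(M) * k, 0);
  std::vector<int> n_kv(static_cast<size_t>(k) * V, 0);
  std::vector<int> n_k(k, 0);

  for (int m = 0; m < M; ++m) {
    z[m].resize(w[m].size());
    for (size_t i = 0; i < w[m].size(); ++i) {
      int t = static_cast<int>(unif(rng) * k);
      if (t == k) t = k - 1;
      z[m][i] = t;
      ++n_dk[static_cast<size_t>(m) * k + t];
      ++n_kv[static_cast<size_t>(t) * V + w[m][i]];
      ++n_k[t];
    }
  }

  std::vector<double> p(k);
  const double Veta = V * eta;
  for (int it = 0; it < iterations; ++it) {
    for (int m = 0; m < M; ++m) {
      int* dk = &n_dk[static_cast<size_t>(m) * k];
      for (size_t i = 0; i < w[m].size(); ++i) {
        const int v = w[m][i];
        const int told = z[m][i];
        --dk[told];
        --n_kv[static_cast<size_t>(told) * V + v];
        --n_k[told];
        double total = 0.0;
        for (int t = 0; t < k; ++t) {
          total += (dk[t] + alpha) *
                   (n_kv[static_cast<size_t>(t) * V + v] + eta) /
                   (n_k[t] + Veta);
          p[t] = total;
        }
        const double u = unif(rng) * total;
        int tnew = 0;
        while (tnew < k - 1 && p[tnew] < u) ++tnew;
        z[m][i] = tnew;
        ++dk[tnew];
        ++n_kv[static_cast<size_t>(tnew) * V + v];
        ++n_k[tnew];
      }
    }
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix theta(k, M);
  for (int m = 0; m < M; ++m) {
    const double denom = w[m].size() + k * alpha;
    for (int t = 0; t < k; ++t) {
      theta(t, m) = (n_dk[static_cast<size_t>(m) * k + t] + alpha) / denom;
    }
  }
  NumericMatrix beta(k, V);
  for (int t = 0; t < k; ++t) {
    const double denom = n_k[t] + Veta;
    for (int v = 0; v < V; ++v) {
      beta(t, v) = (n_kv[static_cast<size_t>(t) * V + v] + eta) / denom;
    }
  }
  return List::create(Named("theta") = theta, Named("beta") = beta);
}
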