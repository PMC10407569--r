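#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for Latent Dirichlet Allocation.
// docs: list of integer vectors of 0-based term ids; empty docs allowed
// (their theta row falls back to the uniform prior). Uses R's RNG, so the
// caller controls determinism with set.seed().
// [[Rcpp::export]]
List lda_gibbs_cpp(List docs, int n_vocab, int n_topics, double alpha,
                   double beta, int n_iter) {
  const int D = docs.size(), K = n_topics, V = n_vocab;
  std::vector< std::vector<int> > w(D);
  std::vector< std::vector<int> > z(D);
  for (int d = 0; d < D; ++d) {
    IntegerVector dv = docs[d];
    w[d].assign(dv.begin(), dv.end());
    z[d].resize(dv.size());
  }

  std::vector<int> ndk((size_t)D * K, 0), nkv((size_t)K * V, 0), nk(K, 0);
  RNGScope scope;

  // random initial topic assignments
  for (int d = 0; d < D; ++d) {
    for (size_t i = 0; i < w[d].size(); ++i) {
      int k = (int)(unif_rand() * K);
      if (k >= K) k = K - 1;
      z[d][i] = k;
      ndk[(size_t)d * K + k]++;
      nkv[(size_t)k * V + w[d][i]]++;
      nk[k]++;
    }
  }

  std::vector<double> p(K);
  const double Vbeta = V * beta;
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int d = 0; d < D; ++d) {
      for (size_t i = 0; i < w[d].size(); ++i) {
        const int v = w[d][i];
        int k = z[d][i];
        ndk[(size_t)d * K + k]--; nkv[(size_t)k * V + v]--; nk[k]--;
        double tot = 0.0;
        for (int t = 0; t < K; ++t) {
          tot += (ndk[(size_t)d * K + t] + alpha) *
                 (nkv[(size_t)t * V + v] + beta) / (nk[t] + Vbeta);
          p[t] = tot;
        }
        const double u = unif_rand() * tot;
        for (k = 0; k < K - 1; ++k) if (u < p[k]) break;
        z[d][i] = k;
        ndk[(size_t)d * K + k]++; nkv[(size_t)k * V + v]++; nk[k]++;
      }
    }
  }

  NumericMatrix theta(D, K), phi(K, V);
  for (int d = 0; d < D; ++d) {
    const double denom = (double)w[d].size() + K * alpha;
    for (int k = 0; k < K; ++k)
      theta(d, k) = (ndk[(size_t)d * K + k] + alpha) / denom;
  }
  for (int k = 0; k < K; ++k) {
    const double denom = nk[k] + Vbeta;
    for (int v = 0; v < V; ++v)
      phi(k, v) = (nkv[(size_t)k * V + v] + beta) / denom;
  }
  return List::create(_["theta"] = theta, _["phi"] = phi);
}
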