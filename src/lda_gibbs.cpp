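// Collapsed Gibbs sampling for latent Dirichlet allocation.
//
// The sampler is self-contained (own mt19937 RNG seeded explicitly) so that
// fits and inference are bit-reproducible given a seed, independently of R's
// RNG state. Topic-word estimates are the usual smoothed normalized counts
// phi[k][w] = (n_kw + beta) / (n_k + V*beta).

#include <Rcpp.h>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

// Sample an index in [0, K) proportional to weights w (unnormalized).
inline int sample_discrete(const std::vector<double>& w, double total,
                           std::mt19937& rng) {
  std::uniform_real_distribution<double> unif(0.0, total);
  double r = unif(rng);
  double acc = 0.0;
  const int K = static_cast<int>(w.size());
  for (int k = 0; k < K; ++k) {
    acc += w[k];
    if (r <= acc) return k;
  }
  return K - 1;  // numerical slack
}

}  // namespace

// [[Rcpp::export(name = ".lda_gibbs_fit")]]
List lda_gibbs_fit(List docs, int V, int K, double alpha, double beta,
                   int n_iter, int seed) {
  const int D = docs.size();
  std::mt19937 rng(static_cast<unsigned int>(seed));

  std::vector<std::vector<int>> w(D);
  std::vector<std::vector<int>> z(D);
  std::vector<std::vector<int>> ndk(D, std::vector<int>(K, 0));
  std::vector<std::vector<int>> nkw(K, std::vector<int>(V, 0));
  std::vector<int> nk(K, 0);

  std::uniform_int_distribution<int> topic_init(0, K - 1);
  for (int d = 0; d < D; ++d) {
    IntegerVector doc = docs[d];
    w[d].assign(doc.begin(), doc.end());  // 0-based word ids
    z[d].resize(w[d].size());
    for (size_t i = 0; i < w[d].size(); ++i) {
      int k = topic_init(rng);
      z[d][i] = k;
      ndk[d][k]++;
      nkw[k][w[d][i]]++;
      nk[k]++;
    }
  }

  std::vector<double> prob(K);
  const double Vbeta = V * beta;
  for (int it = 0; it < n_iter; ++it) {
    for (int d = 0; d < D; ++d) {
      const size_t Nd = w[d].size();
      for (size_t i = 0; i < Nd; ++i) {
        const int wi = w[d][i];
        const int zi = z[d][i];
        ndk[d][zi]--; nkw[zi][wi]--; nk[zi]--;
        double total = 0.0;
        for (int k = 0; k < K; ++k) {
          double p = (ndk[d][k] + alpha) *
                     (nkw[k][wi] + beta) / (nk[k] + Vbeta);
          prob[k] = p;
          total += p;
        }
        const int knew = sample_discrete(prob, total, rng);
        z[d][i] = knew;
        ndk[d][knew]++; nkw[knew][wi]++; nk[knew]++;
      }
    }
  }

  NumericMatrix topic_word(K, V);
  for (int k = 0; k < K; ++k) {
    const double denom = nk[k] + Vbeta;
    for (int v = 0; v < V; ++v) {
      topic_word(k, v) = (nkw[k][v] + beta) / denom;
    }
  }
  IntegerMatrix doc_topic(D, K);
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) doc_topic(d, k) = ndk[d][k];

  return List::create(_["topic_word"] = topic_word,
                      _["doc_topic_counts"] = doc_topic);
}

// Infer document-topic proportions with the topic-word distributions frozen.
// Proportions are smoothed averages of (n_dk + alpha)/(N_d + K*alpha) over
// the sweeps after burn-in.
// [[Rcpp::export(name = ".lda_gibbs_infer")]]
NumericMatrix lda_gibbs_infer(List docs, NumericMatrix phi, double alpha,
                              int n_iter, int burnin, int seed) {
  const int D = docs.size();
  const int K = phi.nrow();
  std::mt19937 rng(static_cast<unsigned int>(seed));
  NumericMatrix theta(D, K);
  std::vector<double> prob(K);
  std::uniform_int_distribution<int> topic_init(0, K - 1);

  for (int d = 0; d < D; ++d) {
    IntegerVector doc = docs[d];
    const int Nd = doc.size();
    if (Nd == 0) {
      for (int k = 0; k < K; ++k) theta(d, k) = 1.0 / K;
      continue;
    }
    std::vector<int> z(Nd);
    std::vector<int> ndk(K, 0);
    for (int i = 0; i < Nd; ++i) {
      int k = topic_init(rng);
      z[i] = k;
      ndk[k]++;
    }
    std::vector<double> acc(K, 0.0);
    int n_acc = 0;
    for (int it = 0; it < n_iter; ++it) {
      for (int i = 0; i < Nd; ++i) {
        const int wi = doc[i];
        ndk[z[i]]--;
        double total = 0.0;
        for (int k = 0; k < K; ++k) {
          double p = (ndk[k] + alpha) * phi(k, wi);
          prob[k] = p;
          total += p;
        }
        const int knew = sample_discrete(prob, total, rng);
        z[i] = knew;
        ndk[knew]++;
      }
      if (it >= burnin) {
        for (int k = 0; k < K; ++k)
          acc[k] += (ndk[k] + alpha) / (Nd + K * alpha);
        n_acc++;
      }
    }
    for (int k = 0; k < K; ++k) theta(d, k) = acc[k] / n_acc;
    // normalise away accumulation round-off
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += theta(d, k);
    for (int k = 0; k < K; ++k) theta(d, k) /= s;
  }
  return theta;
}
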