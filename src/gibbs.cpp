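#include <Rcpp.h>
using namespace Rcpp;

// Draw an index in [0, K) proportional to the (unnormalized) weights.
// Uses R's RNG stream so results are reproducible under set.seed().
static inline int sample_index(const std::vector<double>& p, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  int K = static_cast<int>(p.size());
  for (int k = 0; k < K; ++k) {
    acc += p[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

// Collapsed Gibbs sampler for the biterm topic model.
// biterms: |B| x 2 matrix of 0-based word indices; returns final counts and
// assignments (0-based topics).
// [[Rcpp::export(.btm_gibbs)]]
List btm_gibbs(IntegerMatrix biterms, int M, int K,
               double alpha, double beta, int iters) {
  int B = biterms.nrow();
  std::vector<int> z(B);
  std::vector<double> nk(K, 0.0);
  NumericMatrix nwk(K, M);
  std::vector<double> p(K);

  for (int b = 0; b < B; ++b) {
    int k = static_cast<int>(unif_rand() * K);
    if (k == K) k = K - 1;
    z[b] = k;
    nk[k] += 1.0;
    nwk(k, biterms(b, 0)) += 1.0;
    nwk(k, biterms(b, 1)) += 1.0;
  }

  double Mb = M * beta;
  for (int it = 0; it < iters; ++it) {
    for (int b = 0; b < B; ++b) {
      int w1 = biterms(b, 0), w2 = biterms(b, 1), k = z[b];
      nk[k] -= 1.0;
      nwk(k, w1) -= 1.0;
      nwk(k, w2) -= 1.0;
      double total = 0.0;
      for (int t = 0; t < K; ++t) {
        double denom = (2.0 * nk[t] + Mb) * (2.0 * nk[t] + 1.0 + Mb);
        p[t] = (nk[t] + alpha) * (nwk(t, w1) + beta) *
               (nwk(t, w2) + beta) / denom;
        total += p[t];
      }
      k = sample_index(p, total);
      z[b] = k;
      nk[k] += 1.0;
      nwk(k, w1) += 1.0;
      nwk(k, w2) += 1.0;
    }
  }
  return List::create(_["nk"] = NumericVector(nk.begin(), nk.end()),
                      _["nwk"] = nwk,
                      _["z"] = IntegerVector(z.begin(), z.end()));
}

// Collapsed Gibbs sampler for LDA over per-token topic assignments.
// doc/word: parallel 0-based token vectors.
// [[Rcpp::export(.lda_gibbs)]]
List lda_gibbs(IntegerVector doc, IntegerVector word, int D, int M, int K,
               double alpha, double beta, int iters) {
  int N = doc.size();
  std::vector<int> z(N);
  NumericMatrix ndk(D, K), nwk(K, M);
  std::vector<double> nk(K, 0.0);
  std::vector<double> p(K);

  for (int n = 0; n < N; ++n) {
    int k = static_cast<int>(unif_rand() * K);
    if (k == K) k = K - 1;
    z[n] = k;
    ndk(doc[n], k) += 1.0;
    nwk(k, word[n]) += 1.0;
    nk[k] += 1.0;
  }

  double Mb = M * beta;
  for (int it = 0; it < iters; ++it) {
    for (int n = 0; n < N; ++n) {
      int d = doc[n], w = word[n], k = z[n];
      ndk(d, k) -= 1.0;
      nwk(k, w) -= 1.0;
      nk[k] -= 1.0;
      double total = 0.0;
      for (int t = 0; t < K; ++t) {
        p[t] = (ndk(d, t) + alpha) * (nwk(t, w) + beta) / (nk[t] + Mb);
        total += p[t];
      }
      k = sample_index(p, total);
      z[n] = k;
      ndk(d, k) += 1.0;
      nwk(k, w) += 1.0;
      nk[k] += 1.0;
    }
  }
  return List::create(_["ndk"] = ndk, _["nwk"] = nwk,
                      _["z"] = IntegerVector(z.begin(), z.end()));
}

// Fold-in inference for held-out LDA documents: topic-word distributions are
// fixed at phi, only document-topic counts are sampled.
// [[Rcpp::export(.lda_infer)]]
NumericMatrix lda_infer(IntegerVector doc, IntegerVector word,
                        NumericMatrix phi, int D, double alpha, int iters) {
  int N = doc.size();
  int K = phi.nrow();
  std::vector<int> z(N);
  NumericMatrix ndk(D, K);
  std::vector<double> p(K);

  for (int n = 0; n < N; ++n) {
    int k = static_cast<int>(unif_rand() * K);
    if (k == K) k = K - 1;
    z[n] = k;
    ndk(doc[n], k) += 1.0;
  }
  for (int it = 0; it < iters; ++it) {
    for (int n = 0; n < N; ++n) {
      int d = doc[n], w = word[n], k = z[n];
      ndk(d, k) -= 1.0;
      double total = 0.0;
      for (int t = 0; t < K; ++t) {
        p[t] = (ndk(d, t) + alpha) * phi(t, w);
        total += p[t];
      }
      k = sample_index(p, total);
      z[n] = k;
      ndk(d, k) += 1.0;
    }
  }
  return ndk;
}
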