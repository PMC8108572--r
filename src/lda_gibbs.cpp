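#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// tokens: 0-based word ids, all documents concatenated
// doc:    0-based document index per token, non-decreasing
// The point estimates use the final-state counts plus priors; no sample
// averaging, so a fixed epoch budget gives comparable runs across K.
//
// Reproducibility: draws come from R's RNG (unif_rand), so a set.seed()
// on the R side makes the fit bit-for-bit repeatable.
// [[Rcpp::export(name = ".lda_gibbs")]]
List lda_gibbs(IntegerVector tokens, IntegerVector doc,
               int n_docs, int vocab_size, int K,
               int epochs, double alpha, double beta) {
  int N = tokens.size();
  IntegerMatrix nkw(K, vocab_size);  // topic-word counts
  IntegerMatrix ndk(n_docs, K);      // doc-topic counts
  IntegerVector nk(K);               // tokens per topic
  IntegerVector z(N);

  RNGScope scope;

  // random initial assignment
  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[i] = k;
    nkw(k, tokens[i])++;
    ndk(doc[i], k)++;
    nk[k]++;
  }

  std::vector<double> p(K);
  double Vbeta = vocab_size * beta;

  for (int sweep = 0; sweep < epochs; ++sweep) {
    for (int i = 0; i < N; ++i) {
      int w = tokens[i], d = doc[i], k = z[i];
      nkw(k, w)--; ndk(d, k)--; nk[k]--;
      double tot = 0.0;
      for (int t = 0; t < K; ++t) {
        p[t] = (ndk(d, t) + alpha) * (nkw(t, w) + beta) / (nk[t] + Vbeta);
        tot += p[t];
      }
      double u = unif_rand() * tot;
      int t = 0;
      double acc = p[0];
      while (u > acc && t < K - 1) { acc += p[++t]; }
      z[i] = t;
      nkw(t, w)++; ndk(d, t)++; nk[t]++;
    }
  }

  NumericMatrix topic_word(K, vocab_size);
  for (int k = 0; k < K; ++k) {
    double denom = nk[k] + Vbeta;
    for (int w = 0; w < vocab_size; ++w) {
      topic_word(k, w) = (nkw(k, w) + beta) / denom;
    }
  }
  NumericMatrix doc_topic(n_docs, K);
  for (int d = 0; d < n_docs; ++d) {
    double nd = 0.0;
    for (int k = 0; k < K; ++k) nd += ndk(d, k);
    double denom = nd + K * alpha;
    for (int k = 0; k < K; ++k) {
      doc_topic(d, k) = (ndk(d, k) + alpha) / denom;
    }
  }

  return List::create(_["topic_word"] = topic_word,
                      _["doc_topic"] = doc_topic,
                      _["z"] = z);
}
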