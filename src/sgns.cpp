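// Skip-gram with negative sampling over integer-coded token sequences.
// Single-threaded with its own mt19937 stream so a fixed seed gives
// bit-identical embeddings.  Returns the input-side embedding matrix
// (the |V| x d weight matrix of the two-layer network).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
arma::mat sgns_train_cpp(const Rcpp::List& docs, int V, int d, int window,
                         int negative, int epochs, double lr0, int seed) {
  // unigram counts -> sampling table with the standard 3/4 power
  std::vector<double> counts(V, 0.0);
  long long total_tokens = 0;
  for (int i = 0; i < docs.size(); i++) {
    IntegerVector doc = docs[i];
    for (int j = 0; j < doc.size(); j++) {
      counts[doc[j]] += 1.0;
      total_tokens++;
    }
  }
  std::vector<double> cdf(V);
  double acc = 0.0;
  for (int v = 0; v < V; v++) {
    acc += std::pow(counts[v], 0.75);
    cdf[v] = acc;
  }
  for (int v = 0; v < V; v++) cdf[v] /= acc;

  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  auto draw_neg = [&]() {
    double u = unif(rng);
    return (int)(std::lower_bound(cdf.begin(), cdf.end(), u) - cdf.begin());
  };

  std::uniform_real_distribution<double> init(-0.5 / d, 0.5 / d);
  arma::mat Win(V, d), Wout(V, d, arma::fill::zeros);
  for (int v = 0; v < V; v++)
    for (int j = 0; j < d; j++) Win(v, j) = init(rng);

  auto sigmoid = [](double x) { return 1.0 / (1.0 + std::exp(-x)); };

  double total_work = (double)epochs * (double)total_tokens;
  double done = 0.0;
  std::vector<double> gin(d);
  for (int ep = 0; ep < epochs; ep++) {
    for (int i = 0; i < docs.size(); i++) {
      IntegerVector doc = docs[i];
      int n = doc.size();
      for (int c = 0; c < n; c++) {
        double lr = lr0 * std::max(1.0 - done / total_work, 1e-4);
        done += 1.0;
        int wc = doc[c];
        for (int off = -window; off <= window; off++) {
          if (off == 0) continue;
          int t = c + off;
          if (t < 0 || t >= n) continue;
          int ctx = doc[t];
          std::fill(gin.begin(), gin.end(), 0.0);
          for (int s = 0; s <= negative; s++) {
            int target;
            double label;
            if (s == 0) {
              target = ctx;
              label = 1.0;
            } else {
              target = draw_neg();
              if (target == ctx) continue;
              label = 0.0;
            }
            double dot = 0.0;
            for (int j = 0; j < d; j++) dot += Win(wc, j) * Wout(target, j);
            double grad = (sigmoid(dot) - label) * lr;
            for (int j = 0; j < d; j++) {
              gin[j] += grad * Wout(target, j);
              Wout(target, j) -= grad * Win(wc, j);
            }
          }
          for (int j = 0; j < d; j++) Win(wc, j) -= gin[j];
        }
      }
    }
  }
  return Win;
}
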