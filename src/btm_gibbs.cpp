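#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for the biterm topic model.
//
// Each biterm b = (w1, w2) carries one topic assignment z_b. A sweep
// resamples every biterm from
//   P(z_b = k | z_-b, B) ~ (n_k + alpha) *
//       (n_{w1,k} + beta)(n_{w2,k} + beta) / (sum_w n_{wk} + W beta)^2
// where n_k counts biterms in topic k and n_{wk} counts word slots
// (sum_w n_{wk} = 2 n_k). Uses R's RNG, so results are reproducible under
// set.seed() on the R side.
//
// w1, w2: 1-based word ids; checkpoint_iters: sweeps (1-based) after which
// a snapshot of (n_k, n_wk) is stored.
// [[Rcpp::export]]
List btm_gibbs_cpp(IntegerVector w1, IntegerVector w2, int W, int K,
                   double alpha, double beta, int n_iter,
                   IntegerVector checkpoint_iters) {
  const int B = w1.size();
  IntegerVector z(B);
  NumericVector n_k(K);
  NumericMatrix n_wk(W, K);

  for (int b = 0; b < B; ++b) {
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[b] = k;
    n_k[k] += 1.0;
    n_wk(w1[b] - 1, k) += 1.0;
    n_wk(w2[b] - 1, k) += 1.0;
  }

  std::vector<bool> is_ckpt(n_iter + 1, false);
  for (int i = 0; i < checkpoint_iters.size(); ++i) {
    int it = checkpoint_iters[i];
    if (it >= 1 && it <= n_iter) is_ckpt[it] = true;
  }
  List checkpoints;

  std::vector<double> prob(K);
  const double Wbeta = W * beta;
  for (int iter = 1; iter <= n_iter; ++iter) {
    for (int b = 0; b < B; ++b) {
      const int i1 = w1[b] - 1, i2 = w2[b] - 1;
      int k = z[b];
      n_k[k] -= 1.0;
      n_wk(i1, k) -= 1.0;
      n_wk(i2, k) -= 1.0;

      double total = 0.0;
      for (int j = 0; j < K; ++j) {
        const double denom = 2.0 * n_k[j] + Wbeta;
        const double p = (n_k[j] + alpha) *
          (n_wk(i1, j) + beta) * (n_wk(i2, j) + beta) / (denom * denom);
        total += p;
        prob[j] = total;
      }
      const double u = unif_rand() * total;
      int knew = 0;
      while (knew < K - 1 && prob[knew] < u) ++knew;

      z[b] = knew;
      n_k[knew] += 1.0;
      n_wk(i1, knew) += 1.0;
      n_wk(i2, knew) += 1.0;
    }
    if (is_ckpt[iter]) {
      checkpoints.push_back(List::create(
        _["iter"] = iter,
        _["n_k"] = clone(n_k),
        _["n_wk"] = clone(n_wk)));
    }
  }

  return List::create(
    _["z"] = z + 1,  // 1-based topics for R
    _["n_k"] = n_k,
    _["n_wk"] = n_wk,
    _["checkpoints"] = checkpoints);
}
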