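#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation on an
// instance x feature count matrix, with scalar symmetric Dirichlet
// hyperparameters alpha (instance mixtures) and beta (feature emissions)
// updated by log-normal random-walk Metropolis steps against
// Gamma(shape, rate) hyperpriors.
//
// Uses R's RNG throughout so results are governed by set.seed().

static double loglik_alpha_part(const IntegerMatrix &ndk,
                                const IntegerVector &nd,
                                double a, int D, int K) {
  double ll = D * (R::lgammafn(K * a) - K * R::lgammafn(a));
  for (int d = 0; d < D; d++) {
    for (int k = 0; k < K; k++) ll += R::lgammafn(ndk(d, k) + a);
    ll -= R::lgammafn(nd[d] + K * a);
  }
  return ll;
}

static double loglik_beta_part(const IntegerMatrix &nkv,
                               const IntegerVector &nk,
                               double b, int K, int V) {
  double ll = K * (R::lgammafn(V * b) - V * R::lgammafn(b));
  for (int k = 0; k < K; k++) {
    for (int v = 0; v < V; v++) ll += R::lgammafn(nkv(k, v) + b);
    ll -= R::lgammafn(nk[k] + V * b);
  }
  return ll;
}

// [[Rcpp::export(name = ".lda_gibbs_cpp")]]
List lda_gibbs_cpp(IntegerMatrix counts, int K, int n_sweeps, int burn_in,
                   int thin, double alpha_init, double beta_init,
                   bool update_hyper, double hyper_shape, double hyper_rate,
                   double mh_step) {
  const int D = counts.nrow();
  const int V = counts.ncol();

  // token expansion
  std::vector<int> tok_d, tok_v;
  for (int d = 0; d < D; d++)
    for (int v = 0; v < V; v++)
      for (int c = 0; c < counts(d, v); c++) {
        tok_d.push_back(d);
        tok_v.push_back(v);
      }
  const int N = (int)tok_d.size();
  if (N == 0) stop("activation count matrix has no tokens");

  IntegerMatrix ndk(D, K), nkv(K, V);
  IntegerVector nd(D), nk(K);
  std::vector<int> z(N);

  double alpha = alpha_init, beta = beta_init;

  // random initial assignment
  for (int i = 0; i < N; i++) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[i] = k;
    ndk(tok_d[i], k)++;
    nkv(k, tok_v[i])++;
    nd[tok_d[i]]++;
    nk[k]++;
  }

  NumericMatrix theta_acc(D, K), phi_acc(K, V);
  NumericVector logjoint(n_sweeps), alpha_trace(n_sweeps), beta_trace(n_sweeps);
  int n_samples = 0;
  std::vector<double> p(K);

  for (int sweep = 0; sweep < n_sweeps; sweep++) {
    for (int i = 0; i < N; i++) {
      const int d = tok_d[i], v = tok_v[i], kold = z[i];
      ndk(d, kold)--;
      nkv(kold, v)--;
      nd[d]--;
      nk[kold]--;
      double tot = 0.0;
      for (int k = 0; k < K; k++) {
        p[k] = (ndk(d, k) + alpha) * (nkv(k, v) + beta) / (nk[k] + V * beta);
        tot += p[k];
      }
      double u = unif_rand() * tot;
      int knew = 0;
      double cum = p[0];
      while (u > cum && knew < K - 1) cum += p[++knew];
      z[i] = knew;
      ndk(d, knew)++;
      nkv(knew, v)++;
      nd[d]++;
      nk[knew]++;
    }

    if (update_hyper) {
      // alpha
      double prop = alpha * std::exp(mh_step * norm_rand());
      double la = loglik_alpha_part(ndk, nd, prop, D, K) -
                  loglik_alpha_part(ndk, nd, alpha, D, K) +
                  (hyper_shape - 1.0) * (std::log(prop) - std::log(alpha)) -
                  hyper_rate * (prop - alpha) +
                  (std::log(prop) - std::log(alpha));  // proposal asymmetry
      if (std::log(unif_rand()) < la) alpha = prop;
      // beta
      prop = beta * std::exp(mh_step * norm_rand());
      la = loglik_beta_part(nkv, nk, prop, K, V) -
           loglik_beta_part(nkv, nk, beta, K, V) +
           (hyper_shape - 1.0) * (std::log(prop) - std::log(beta)) -
           hyper_rate * (prop - beta) +
           (std::log(prop) - std::log(beta));
      if (std::log(unif_rand()) < la) beta = prop;
    }

    logjoint[sweep] = loglik_alpha_part(ndk, nd, alpha, D, K) +
                      loglik_beta_part(nkv, nk, beta, K, V);
    alpha_trace[sweep] = alpha;
    beta_trace[sweep] = beta;

    if (sweep >= burn_in && ((sweep - burn_in) % thin == 0)) {
      for (int d = 0; d < D; d++)
        for (int k = 0; k < K; k++)
          theta_acc(d, k) += (ndk(d, k) + alpha) / (nd[d] + K * alpha);
      for (int k = 0; k < K; k++)
        for (int v = 0; v < V; v++)
          phi_acc(k, v) += (nkv(k, v) + beta) / (nk[k] + V * beta);
      n_samples++;
    }
  }

  if (n_samples > 0) {
    for (int d = 0; d < D; d++)
      for (int k = 0; k < K; k++) theta_acc(d, k) /= n_samples;
    for (int k = 0; k < K; k++)
      for (int v = 0; v < V; v++) phi_acc(k, v) /= n_samples;
  }

  return List::create(_["theta"] = theta_acc, _["phi"] = phi_acc,
                      _["alpha"] = alpha, _["beta"] = beta,
                      _["log_joint"] = logjoint,
                      _["alpha_trace"] = alpha_trace,
                      _["beta_trace"] = beta_trace,
                      _["n_samples"] = n_samples, _["n_tokens"] = N);
}
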