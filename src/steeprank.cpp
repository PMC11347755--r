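#include <Rcpp.h>
using namespace Rcpp;

// Sequential Elo over one interaction sequence. winners/losers are 0-based
// indices into 1..n_ids. Expected win probability uses the classical
// logistic-base-10 curve with width `scale`; updates are zero-sum.
// [[Rcpp::export]]
NumericVector elo_run_cpp(IntegerVector winners, IntegerVector losers,
                          int n_ids, double k, double start, double scale) {
  NumericVector r(n_ids, start);
  int m = winners.size();
  for (int e = 0; e < m; ++e) {
    int w = winners[e], l = losers[e];
    double e_win = 1.0 / (1.0 + std::pow(10.0, (r[l] - r[w]) / scale));
    double upd = k * (1.0 - e_win);
    r[w] += upd;
    r[l] -= upd;
  }
  return r;
}

static inline double dyad_loglik(double ai, double aj, double sij, double sji) {
  // Binomial kernel for one dyad with win probability logistic(ai - aj)
  double d = ai - aj;
  // log(p) = -log1p(exp(-d)), log(1-p) = -d - log1p(exp(-d))
  double l1p = (d > 0) ? std::log1p(std::exp(-d)) : -d + std::log1p(std::exp(d));
  return -sij * l1p - sji * (d + l1p);
}

// Random-walk Metropolis on latent strengths a (std-normal prior, iid),
// component-wise sweeps. Uses R's RNG so set.seed() governs reproducibility.
// Returns kept draws (rows) of the centered strength vector.
// [[Rcpp::export]]
NumericMatrix latent_strength_mcmc_cpp(NumericMatrix s, int n_iter, int burn_in,
                                       double proposal_sd,
                                       NumericVector a_init) {
  int n = s.nrow();
  std::vector<double> a(a_init.begin(), a_init.end());
  NumericMatrix out(n_iter, n);
  RNGScope scope;
  for (int it = 0; it < burn_in + n_iter; ++it) {
    for (int i = 0; i < n; ++i) {
      double prop = a[i] + R::rnorm(0.0, proposal_sd);
      double dll = 0.5 * (a[i] * a[i] - prop * prop);  // prior N(0,1)
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double sij = s(i, j), sji = s(j, i);
        if (sij + sji > 0) {
          dll += dyad_loglik(prop, a[j], sij, sji)
               - dyad_loglik(a[i], a[j], sij, sji);
        }
      }
      if (dll >= 0 || R::runif(0.0, 1.0) < std::exp(dll)) a[i] = prop;
    }
    if (it >= burn_in) {
      double mean_a = 0.0;
      for (int i = 0; i < n; ++i) mean_a += a[i];
      mean_a /= n;
      for (int i = 0; i < n; ++i) out(it - burn_in, i) = a[i] - mean_a;
    }
  }
  return out;
}
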