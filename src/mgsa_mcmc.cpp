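// Metropolis sampler for the model-based gene set analysis posterior.
//
// Model: each set k carries a hidden activation state a_k ~ Bernoulli(p).
// A gene is hidden-on iff it belongs to >=1 active set.  The observed study
// set arises by flipping hidden states: P(observed | hidden=0) = alpha,
// P(not observed | hidden=1) = beta.  Hyperparameters alpha, beta, p are
// either fixed (grid of length 1) or discrete grids with a uniform prior,
// marginalized by extra proposal moves.
//
// Sufficient statistics maintained incrementally: among hidden-on genes the
// number observed (t1) and not observed (f1); with O = total observed and
// G genes, the log-likelihood is
//   (O - t1) log a + (G - O - f1) log(1 - a) + f1 log b + t1 log(1 - b).

#include <Rcpp.h>
#include <random>
using namespace Rcpp;

static inline double loglik(int t1, int f1, int nA, int K, int O, int G,
                            double a, double b, double p) {
  return (O - t1) * std::log(a) + (G - O - f1) * std::log(1.0 - a) +
         f1 * std::log(b) + t1 * std::log(1.0 - b) +
         nA * std::log(p) + (K - nA) * std::log(1.0 - p);
}

// [[Rcpp::export]]
List mgsa_mcmc_cpp(List sets, int n_genes, IntegerVector observed,
                   NumericVector alpha_grid, NumericVector beta_grid,
                   NumericVector p_grid, double n_steps, double burn_in,
                   int seed, double hyper_move_prob) {
  const int K = sets.size();
  const int G = n_genes;
  std::vector<std::vector<int>> mem(K);
  for (int k = 0; k < K; ++k) {
    IntegerVector s = sets[k];
    mem[k].assign(s.begin(), s.end());  // 0-based gene indices
  }
  std::vector<int> obs(observed.begin(), observed.end());
  int O = 0;
  for (int g = 0; g < G; ++g) O += obs[g];

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> runif(0.0, 1.0);
  std::uniform_int_distribution<int> rset(0, K - 1);

  std::vector<int> a(K, 0), cnt(G, 0);
  int t1 = 0, f1 = 0, nA = 0;
  int ia = 0, ib = 0, ip = 0;

  const bool grid_a = alpha_grid.size() > 1;
  const bool grid_b = beta_grid.size() > 1;
  const bool grid_p = p_grid.size() > 1;
  int n_grids = (grid_a ? 1 : 0) + (grid_b ? 1 : 0) + (grid_p ? 1 : 0);
  double p_hyper = (n_grids > 0) ? hyper_move_prob : 0.0;

  double cur = loglik(t1, f1, nA, K, O, G, alpha_grid[ia], beta_grid[ib],
                      p_grid[ip]);

  std::vector<double> a_sum(K, 0.0);
  double asum = 0.0, bsum = 0.0, psum = 0.0;
  double accepted = 0.0;
  const double total = n_steps;
  const double keep = total - burn_in;

  for (double step = 0; step < total; ++step) {
    if (runif(rng) < p_hyper) {
      // independence proposal on one gridded hyperparameter (symmetric)
      int which = (int)(runif(rng) * n_grids);
      int gi = -1;
      if (grid_a && which-- == 0) gi = 0;
      else if (grid_b && which-- == 0) gi = 1;
      else gi = 2;
      int ja = ia, jb = ib, jp = ip;
      if (gi == 0) ja = (int)(runif(rng) * alpha_grid.size());
      else if (gi == 1) jb = (int)(runif(rng) * beta_grid.size());
      else jp = (int)(runif(rng) * p_grid.size());
      double prop = loglik(t1, f1, nA, K, O, G, alpha_grid[ja],
                           beta_grid[jb], p_grid[jp]);
      if (std::log(runif(rng)) < prop - cur) {
        ia = ja; ib = jb; ip = jp; cur = prop; accepted += 1.0;
      }
    } else {
      // toggle one set's activation state
      int k = rset(rng);
      const std::vector<int>& genes = mem[k];
      int d_t1 = 0, d_f1 = 0;
      if (a[k] == 0) {  // activating: genes with cover count 0 turn on
        for (int g : genes) if (cnt[g] == 0) {
          if (obs[g]) ++d_t1; else ++d_f1;
        }
      } else {          // deactivating: genes covered only by k turn off
        for (int g : genes) if (cnt[g] == 1) {
          if (obs[g]) --d_t1; else --d_f1;
        }
      }
      int d_nA = a[k] == 0 ? 1 : -1;
      double prop = loglik(t1 + d_t1, f1 + d_f1, nA + d_nA, K, O, G,
                           alpha_grid[ia], beta_grid[ib], p_grid[ip]);
      if (std::log(runif(rng)) < prop - cur) {
        int delta = a[k] == 0 ? 1 : -1;
        for (int g : genes) cnt[g] += delta;
        a[k] ^= 1;
        t1 += d_t1; f1 += d_f1; nA += d_nA;
        cur = prop; accepted += 1.0;
      }
    }
    if (step >= burn_in) {
      for (int k = 0; k < K; ++k) a_sum[k] += a[k];
      asum += alpha_grid[ia]; bsum += beta_grid[ib]; psum += p_grid[ip];
    }
  }

  NumericVector est(K);
  for (int k = 0; k < K; ++k) est[k] = a_sum[k] / keep;
  return List::create(
    _["estimate"] = est,
    _["acceptance_rate"] = accepted / total,
    _["alpha_mean"] = asum / keep,
    _["beta_mean"] = bsum / keep,
    _["p_mean"] = psum / keep);
}
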