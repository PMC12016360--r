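#include <Rcpp.h>
using namespace Rcpp;

// Spike-and-slab (point-normal) Gibbs sampler over standardized marginal
// effects with a block-diagonal correlation prior. Hyperparameters:
//   p  ~ Beta(1 + Mc, 1 + M - Mc) each sweep (Mc = current nonzero count)
//   h2 = beta' R beta (blockwise), clamped below at h2_floor
// Per-probe slab variance sigma2 = h2 / (M * p). Uses R's RNG stream, so
// results are reproducible under set.seed() on the R side and depend only on
// the canonical probe order (the wrapper sorts blocks canonically).

// [[Rcpp::export]]
List gibbs_core(List block_idx, List block_R, NumericVector beta_hat,
                NumericVector n, double h2_init, double p_init,
                int burn_in, int n_iter, double h2_floor, double beta_bound,
                bool fix_p, double p_fixed, bool fix_h2, double h2_fixed,
                bool keep_draws) {
  const int M = beta_hat.size();
  const int n_blocks = block_idx.size();
  std::vector<IntegerVector> idx(n_blocks);
  std::vector<NumericMatrix> R(n_blocks);
  for (int b = 0; b < n_blocks; ++b) {
    idx[b] = as<IntegerVector>(block_idx[b]);
    R[b] = as<NumericMatrix>(block_R[b]);
  }

  NumericVector beta(M);
  double p = fix_p ? p_fixed : p_init;
  double h2 = fix_h2 ? h2_fixed : std::max(h2_init, h2_floor);

  NumericVector p_chain(n_iter), h2_chain(n_iter);
  IntegerVector mc_chain(n_iter);
  NumericVector beta_sum(M), beta_sumsq(M);
  IntegerVector incl_count(M);
  NumericMatrix draws = keep_draws ? NumericMatrix(n_iter, M)
                                   : NumericMatrix(0, 0);

  const int total = burn_in + n_iter;
  for (int sweep = 0; sweep < total; ++sweep) {
    const double sigma2 = h2 / (M * p);
    for (int b = 0; b < n_blocks; ++b) {
      const IntegerVector& ix = idx[b];
      const NumericMatrix& Rb = R[b];
      const int K = ix.size();
      for (int j = 0; j < K; ++j) {
        const int jj = ix[j];
        double dot = 0.0;
        for (int k = 0; k < K; ++k) dot += Rb(j, k) * beta[ix[k]];
        const double res = beta_hat[jj] - dot + Rb(j, j) * beta[jj];
        const double nj = n[jj];
        const double ns2 = nj * sigma2;
        const double shrink = 1.0 / (1.0 + 1.0 / ns2);
        const double post_mean = res * shrink;
        const double post_var = shrink / nj;
        double pj;
        if (p >= 1.0) {
          pj = 1.0;
        } else {
          const double log_odds = std::log((1.0 - p) / p)
            + 0.5 * std::log1p(ns2)
            - 0.5 * res * res * nj * nj * sigma2 / (1.0 + ns2);
          pj = 1.0 / (1.0 + std::exp(log_odds));
        }
        const double u = unif_rand();
        double newb = 0.0;
        if (u < pj) newb = post_mean + std::sqrt(post_var) * norm_rand();
        beta[jj] = newb;
        if (std::fabs(newb) > beta_bound) {
          stop("sampler diverged at sweep %d (probe index %d, |beta| = %g > %g); "
               "correlation blocks are likely ill-conditioned",
               sweep + 1, jj + 1, std::fabs(newb), beta_bound);
        }
      }
    }
    // hyperparameter updates aggregate over all blocks
    int Mc = 0;
    for (int j = 0; j < M; ++j) if (beta[j] != 0.0) ++Mc;
    if (!fix_p) p = R::rbeta(1.0 + Mc, 1.0 + M - Mc);
    if (!fix_h2) {
      double q = 0.0;
      for (int b = 0; b < n_blocks; ++b) {
        const IntegerVector& ix = idx[b];
        const NumericMatrix& Rb = R[b];
        const int K = ix.size();
        for (int j = 0; j < K; ++j) {
          double rowdot = 0.0;
          for (int k = 0; k < K; ++k) rowdot += Rb(j, k) * beta[ix[k]];
          q += beta[ix[j]] * rowdot;
        }
      }
      h2 = std::max(q, h2_floor);
    }
    const int kept = sweep - burn_in;
    if (kept >= 0) {
      p_chain[kept] = p;
      h2_chain[kept] = h2;
      mc_chain[kept] = Mc;
      for (int j = 0; j < M; ++j) {
        beta_sum[j] += beta[j];
        beta_sumsq[j] += beta[j] * beta[j];
        if (beta[j] != 0.0) ++incl_count[j];
        if (keep_draws) draws(kept, j) = beta[j];
      }
    }
  }

  NumericVector beta_post(M), beta_sd(M), pip(M);
  for (int j = 0; j < M; ++j) {
    beta_post[j] = beta_sum[j] / n_iter;
    const double ss = beta_sumsq[j] - beta_sum[j] * beta_sum[j] / n_iter;
    beta_sd[j] = n_iter > 1 ? std::sqrt(std::max(ss, 0.0) / (n_iter - 1)) : NA_REAL;
    pip[j] = (double)incl_count[j] / n_iter;
  }

  return List::create(
    _["beta_post"] = beta_post, _["beta_sd"] = beta_sd, _["pip"] = pip,
    _["p_chain"] = p_chain, _["h2_chain"] = h2_chain, _["mc_chain"] = mc_chain,
    _["draws"] = keep_draws ? (SEXP)draws : R_NilValue);
}
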