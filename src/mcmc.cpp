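// MCMC engine for the mixture-prior variance-partitioning model
//   y = X gamma + L a + M beta + e,   u = L a,   e ~ N(0, I sigma_e2)
// with a K-component scale-mixture prior on beta:
//   beta_i | z_i = k ~ N(0, comp_var[k]),  comp_var[k] = base_var * ratio[k]
//   z_i ~ cat(pi),  pi ~ Dirichlet(alpha)
// L is a factor of the relationship matrix (L L' = K_rel), so a has iid
// N(0, sigma_u2) prior and a'a = u' K_rel^{-1} u on the column space.
//
// All randomness goes through the R RNG, so set.seed() gives bit-identical
// chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double log_norm(double x, double var) {
  return -0.5 * (std::log(2.0 * M_PI * var) + x * x / var);
}

// [[Rcpp::export(name = ".mix_mcmc_cpp")]]
List mix_mcmc_cpp(const arma::vec& y,
                  const arma::mat& X,
                  const arma::mat& L,
                  const arma::mat& M,
                  const arma::vec& eigvals,     // L'L diagonal (eigenvalues)
                  int K,
                  const arma::vec& ratios,
                  const arma::vec& alpha,
                  int n_iter, int burn_in, int thin,
                  arma::vec gamma,              // initial values
                  double sigma_e2, double sigma_u2, double base_var,
                  arma::vec pi_vec,
                  bool has_polygenic,
                  bool update_sigma_e, bool update_sigma_u,
                  bool update_comp_var, bool update_pi,
                  double step_sd, bool tune_step,
                  bool save_z, bool save_beta) {
  const int n = y.n_elem;
  const int c = X.n_cols;
  const int q = has_polygenic ? L.n_cols : 0;
  const int p = M.n_cols;
  const double VAR_FLOOR = 1e-12;
  const double VAR_CEIL = 1e12;

  arma::vec a(std::max(q, 1), arma::fill::zeros);
  arma::vec beta(p, arma::fill::zeros);
  arma::ivec z(p, arma::fill::ones);            // all in component 1
  arma::vec comp_var(K);
  for (int k = 0; k < K; ++k) comp_var[k] = base_var * ratios[k];

  arma::vec xsq(std::max(c, 1));
  for (int j = 0; j < c; ++j) xsq[j] = arma::dot(X.col(j), X.col(j));
  arma::vec msq(std::max(p, 1));
  for (int i = 0; i < p; ++i) msq[i] = arma::dot(M.col(i), M.col(i));

  arma::vec r = y - X * gamma;                  // a = 0, beta = 0 at start

  const int n_save = (n_iter - burn_in) / thin;
  arma::vec s_sigma_u2(n_save), s_sigma_e2(n_save), s_base_var(n_save);
  arma::vec s_var_m(n_save), s_deviance(n_save), s_step(n_save);
  arma::mat s_pi(n_save, K);
  arma::imat s_z;   if (save_z) s_z.set_size(p, n_save);
  arma::mat s_beta; if (save_beta) s_beta.set_size(p, n_save);
  arma::mat s_gamma(n_save, std::max(c, 1));
  arma::vec beta_sum(p, arma::fill::zeros), beta2_sum(p, arma::fill::zeros);
  arma::vec fitted_sum(n, arma::fill::zeros);
  arma::vec u_sum(n, arma::fill::zeros);

  int mh_acc = 0, mh_try = 0;         // constrained-variance MH, tuning window
  int z_acc = 0, z_try = 0;
  int isave = 0;

  RNGScope scope;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- fixed effects: single-site Gibbs, flat prior ---
    for (int j = 0; j < c; ++j) {
      double old = gamma[j];
      double rhs = arma::dot(X.col(j), r) + xsq[j] * old;
      double v = sigma_e2 / xsq[j];
      double mu = rhs / xsq[j];
      double nw = mu + std::sqrt(v) * R::norm_rand();
      gamma[j] = nw;
      r += X.col(j) * (old - nw);
    }

    // --- polygenic block: L'L is diagonal, so the full conditional of a is
    //     jointly independent; two dense mat-vec products per iteration ---
    if (has_polygenic) {
      arma::vec rt = r + L * a;                 // residual without u
      arma::vec proj = L.t() * rt;
      for (int j = 0; j < q; ++j) {
        double v = 1.0 / (eigvals[j] / sigma_e2 + 1.0 / sigma_u2);
        a[j] = v * proj[j] / sigma_e2 + std::sqrt(v) * R::norm_rand();
      }
      r = rt - L * a;
    }

    // --- taxon effects: single-site Gibbs with incremental residual ---
    for (int i = 0; i < p; ++i) {
      double s2 = comp_var[z[i] - 1];
      double old = beta[i];
      double rhs = arma::dot(M.col(i), r) + msq[i] * old;
      double v = 1.0 / (msq[i] / sigma_e2 + 1.0 / s2);
      double mu = v * rhs / sigma_e2;
      double nw = mu + std::sqrt(v) * R::norm_rand();
      beta[i] = nw;
      r += M.col(i) * (old - nw);
    }

    // --- component indicators: +/-1 random-walk MH with boundary
    //     corrections (q ratio 0.5 leaving a boundary, 2 entering one) ---
    if (K > 1) {
      for (int i = 0; i < p; ++i) {
        int zc = z[i];
        int zp;
        if (zc == 1)       zp = 2;
        else if (zc == K)  zp = K - 1;
        else               zp = (unif_rand() < 0.5) ? zc - 1 : zc + 1;
        // Hastings correction: a boundary state proposes its neighbour
        // with probability 1, an interior state with probability 0.5; the
        // corrections cancel when both states are boundaries (K = 2)
        double q_fwd = (zc == 1 || zc == K) ? 1.0 : 0.5;
        double q_rev = (zp == 1 || zp == K) ? 1.0 : 0.5;
        double log_q = std::log(q_rev) - std::log(q_fwd);
        double la = std::log(pi_vec[zp - 1]) - std::log(pi_vec[zc - 1])
          + log_norm(beta[i], comp_var[zp - 1])
          - log_norm(beta[i], comp_var[zc - 1]) + log_q;
        ++z_try;
        if (la >= 0.0 || std::log(unif_rand()) < la) { z[i] = zp; ++z_acc; }
      }
    }

    // --- mixture proportions: Dirichlet Gibbs ---
    if (update_pi && K > 1) {
      arma::vec cnt(K, arma::fill::zeros);
      for (int i = 0; i < p; ++i) cnt[z[i] - 1] += 1.0;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        pi_vec[k] = R::rgamma(alpha[k] + cnt[k], 1.0);
        tot += pi_vec[k];
      }
      pi_vec /= tot;
    }

    // --- scalar variances: scaled inverse chi-square, flat priors ---
    if (update_sigma_e) {
      double ee = arma::dot(r, r);
      sigma_e2 = ee / R::rchisq(n - 2);
      if (sigma_e2 < VAR_FLOOR) sigma_e2 = VAR_FLOOR;
    }
    if (has_polygenic && update_sigma_u) {
      double aa = arma::dot(a, a);
      sigma_u2 = aa / R::rchisq(q - 2);
      if (sigma_u2 < VAR_FLOOR) sigma_u2 = VAR_FLOOR;
    }

    // --- constrained component variances: joint log-normal random walk on
    //     the base variance under a flat prior on the variance itself;
    //     acceptance = likelihood ratio of beta times the proposal
    //     Jacobian (prop/base).  Without the Jacobian the implied prior is
    //     flat on log(sigma^2), which is improper at zero and lets the
    //     chain collapse into the degenerate spike at sigma^2 -> 0. ---
    if (update_comp_var) {
      double prop = base_var * std::exp(step_sd * R::norm_rand());
      if (prop < VAR_FLOOR) prop = VAR_FLOOR;
      double lr = std::log(prop) - std::log(base_var);
      for (int k = 0; k < K; ++k) {
        double s2c = base_var * ratios[k];
        double s2p = prop * ratios[k];
        double nk = 0.0, ssq = 0.0;
        for (int i = 0; i < p; ++i) {
          if (z[i] - 1 == k) { nk += 1.0; ssq += beta[i] * beta[i]; }
        }
        lr += -0.5 * nk * std::log(s2p) - 0.5 * ssq / s2p
              + 0.5 * nk * std::log(s2c) + 0.5 * ssq / s2c;
      }
      ++mh_try;
      if (lr >= 0.0 || std::log(unif_rand()) < lr) {
        base_var = prop;
        for (int k = 0; k < K; ++k) comp_var[k] = base_var * ratios[k];
        ++mh_acc;
      }
      if (tune_step && iter <= burn_in && mh_try == 100) {
        double rate = mh_acc / 100.0;
        if (rate < 0.2) step_sd *= 0.8;
        else if (rate > 0.5) step_sd *= 1.25;
        mh_acc = 0; mh_try = 0;
      }
    }

    if (sigma_e2 > VAR_CEIL || sigma_u2 > VAR_CEIL || base_var > VAR_CEIL)
      stop("divergent chain: a variance exceeded 1e12 at iteration %d", iter);

    // --- save ---
    if (iter > burn_in && (iter - burn_in) % thin == 0 && isave < n_save) {
      arma::vec mb = M * beta;
      s_var_m[isave] = (n > 1) ? arma::var(mb) : 0.0;   // divisor n-1
      s_sigma_u2[isave] = has_polygenic ? sigma_u2 : 0.0;
      s_sigma_e2[isave] = sigma_e2;
      s_base_var[isave] = base_var;
      s_step[isave] = step_sd;
      for (int k = 0; k < K; ++k) s_pi(isave, k) = pi_vec[k];
      for (int j = 0; j < c; ++j) s_gamma(isave, j) = gamma[j];
      if (save_z) for (int i = 0; i < p; ++i) s_z(i, isave) = z[i];
      if (save_beta) for (int i = 0; i < p; ++i) s_beta(i, isave) = beta[i];
      beta_sum += beta;
      beta2_sum += arma::square(beta);
      arma::vec fitted = y - r;
      fitted_sum += fitted;
      if (has_polygenic) u_sum += L * a;
      double ee = arma::dot(r, r);
      s_deviance[isave] = n * std::log(2.0 * M_PI * sigma_e2) + ee / sigma_e2;
      ++isave;
    }
  }

  List out = List::create(
    Named("sigma_u2") = s_sigma_u2, Named("sigma_e2") = s_sigma_e2,
    Named("base_var") = s_base_var, Named("var_m") = s_var_m,
    Named("pi") = s_pi, Named("gamma") = s_gamma,
    Named("deviance") = s_deviance, Named("step_sd") = s_step,
    Named("beta_mean") = beta_sum / std::max(isave, 1),
    Named("beta2_mean") = beta2_sum / std::max(isave, 1),
    Named("fitted_mean") = fitted_sum / std::max(isave, 1),
    Named("u_mean") = u_sum / std::max(isave, 1),
    Named("n_saved") = isave,
    Named("z_accept") = z_try > 0 ? (double)z_acc / z_try : NA_REAL);
  if (save_z) out["z"] = s_z;
  if (save_beta) out["beta"] = s_beta;
  return out;
}
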