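// Metropolis-within-Gibbs sampler for the joint Bayesian measurement-error
// model: conditional logistic disease model x normal measurement model x
// two-level multivariate-normal exposure model x diffuse priors.
//
// Layout conventions (enforced on the R side before calling):
//   * subjects are row-ordered by matched set, case first within each set;
//   * set_start / set_size are 0-based row offsets into W, Z, X;
//   * Sigma (measurement error covariance) is diagonal, passed as sigma2.
//
// Uses R's RNG throughout (RNGScope via Rcpp attributes) so that
// set.seed() on the R side gives bit-identical chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double lse_set(const arma::vec& eta, arma::uword s, arma::uword n) {
  double m = eta(s);
  for (arma::uword j = 1; j < n; ++j) m = std::max(m, eta(s + j));
  double acc = 0.0;
  for (arma::uword j = 0; j < n; ++j) acc += std::exp(eta(s + j) - m);
  return m + std::log(acc);
}

// conditional logistic log-likelihood, case first in each set
static double log_disease_eta(const arma::vec& eta,
                              const arma::uvec& set_start,
                              const arma::uvec& set_size) {
  double out = 0.0;
  for (arma::uword i = 0; i < set_start.n_elem; ++i)
    out += eta(set_start(i)) - lse_set(eta, set_start(i), set_size(i));
  return out;
}

// log multivariate-gamma
static double lmvgamma(int p, double a) {
  double out = 0.25 * p * (p - 1) * std::log(M_PI);
  for (int i = 1; i <= p; ++i) out += R::lgammafn(a + 0.5 * (1 - i));
  return out;
}

// Wishart log-density of S ~ W_P(R, b), R the positive-definite INVERSE
// scale matrix (density \propto |S|^{(b-P-1)/2} exp(-tr(R S)/2))
static double log_dwishart(const arma::mat& S, const arma::mat& R, double b) {
  int p = S.n_rows;
  double ldS, sgn, ldR;
  arma::log_det(ldS, sgn, S);
  arma::log_det(ldR, sgn, R);
  return 0.5 * b * ldR + 0.5 * (b - p - 1) * ldS - 0.5 * arma::trace(R * S) -
         0.5 * b * p * M_LN2 - lmvgamma(p, 0.5 * b);
}

// draw from W_P(df, S) with SCALE matrix S (Bartlett decomposition)
static arma::mat rwishart(double df, const arma::mat& S) {
  int p = S.n_rows;
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

static arma::vec rnorm_vec(arma::uword n) {
  arma::vec z(n);
  for (arma::uword i = 0; i < n; ++i) z(i) = R::norm_rand();
  return z;
}

// multivariate normal log-density with precision Q (ldQ = log|Q|)
static double log_dmvnorm_prec(const arma::vec& x, const arma::vec& m,
                               const arma::mat& Q, double ldQ) {
  arma::vec d = x - m;
  return 0.5 * ldQ - 0.5 * x.n_elem * std::log(2.0 * M_PI) -
         0.5 * arma::as_scalar(d.t() * Q * d);
}

// [[Rcpp::export]]
List cpp_run_chain(const arma::mat& W, const arma::mat& Z,
                   const arma::uvec& set_start, const arma::uvec& set_size,
                   const arma::vec& sigma2, const arma::vec& mu,
                   double beta_var, double delta_var,
                   const arma::mat& wish_R, double wish_df,
                   int n_iter, int n_burn, int adapt_window,
                   double step_x, double step_b, int n_bd_updates,
                   bool naive, bool fix_cov, bool include_disease,
                   arma::mat X, arma::mat M,
                   arma::mat VW, arma::mat VB,
                   arma::vec beta, arma::vec delta) {
  const arma::uword n = W.n_rows, P = W.n_cols, K = Z.n_cols,
                    N = set_start.n_elem, D = P + K;
  const arma::uword n_adapt = std::min<arma::uword>(n_burn, adapt_window);

  arma::mat draws_beta(n_iter, P), draws_delta(n_iter, std::max<arma::uword>(K, 1)),
      draws_vw(n_iter, naive ? 1 : P * P), draws_vb(n_iter, naive ? 1 : P * P);
  arma::vec lp_trace(n_iter);

  arma::mat invVW, invVB;
  double ldVWinv = 0.0, ldVBinv = 0.0;
  if (!naive) {
    invVW = arma::inv_sympd(VW);
    invVB = arma::inv_sympd(VB);
    double sgn;
    arma::log_det(ldVWinv, sgn, invVW);
    arma::log_det(ldVBinv, sgn, invVB);
  }

  // linear predictor eta_ij = X_ij' beta + Z_ij' delta (X == W when naive)
  const arma::mat& Xcur = naive ? W : X;
  arma::vec eta = (naive ? W : X) * beta;
  if (K > 0) eta += Z * delta;

  // per-coordinate proposal scale for latent X: conditional-sd shaped
  arma::vec prop_sd_x(P, arma::fill::zeros);
  auto refresh_prop_x = [&]() {
    for (arma::uword p = 0; p < P; ++p)
      prop_sd_x(p) = 1.0 / std::sqrt(1.0 / sigma2(p) + invVW(p, p));
  };
  if (!naive) refresh_prop_x();

  // adaptive (diagonal) proposal for (beta, delta): Welford running moments
  arma::vec bd_mean(D, arma::fill::zeros), bd_m2(D, arma::fill::zeros),
      bd_sd(D, arma::fill::ones);
  bd_sd *= 0.1;
  arma::uword bd_n = 0;

  double acc_x_sum = 0.0, acc_b_sum = 0.0;  // post-burn-in tallies
  arma::uword n_post = 0;

  const double prior_b_prec = 1.0 / beta_var, prior_d_prec = 1.0 / delta_var;

  for (int it = 0; it < n_iter; ++it) {
    if (it % 4096 == 0) Rcpp::checkUserInterrupt();
    double acc_x_it = 0.0, acc_b_it = 0.0;

    if (!naive) {
      // --- block 1: set means M_i | X, VW, VB, mu (conjugate MVN) ---
      for (arma::uword i = 0; i < N; ++i) {
        arma::mat Q = invVB + double(set_size(i)) * invVW;
        arma::vec sx(P, arma::fill::zeros);
        for (arma::uword j = 0; j < set_size(i); ++j)
          sx += X.row(set_start(i) + j).t();
        arma::vec b = invVB * mu + invVW * sx;
        arma::mat C = arma::inv_sympd(Q);
        M.row(i) = (C * b + arma::chol(C, "lower") * rnorm_vec(P)).t();
      }

      // --- block 2: precision matrices | rest (conjugate Wishart) ---
      if (!fix_cov) {
        arma::mat SW(P, P, arma::fill::zeros), SB(P, P, arma::fill::zeros);
        for (arma::uword i = 0; i < N; ++i) {
          for (arma::uword j = 0; j < set_size(i); ++j) {
            arma::vec d = X.row(set_start(i) + j).t() - M.row(i).t();
            SW += d * d.t();
          }
          arma::vec d = M.row(i).t() - mu;
          SB += d * d.t();
        }
        invVW = rwishart(wish_df + double(n), arma::inv_sympd(wish_R + SW));
        invVB = rwishart(wish_df + double(N), arma::inv_sympd(wish_R + SB));
        VW = arma::inv_sympd(invVW);
        VB = arma::inv_sympd(invVB);
        double sgn;
        arma::log_det(ldVWinv, sgn, invVW);
        arma::log_det(ldVBinv, sgn, invVB);
        refresh_prop_x();
      }

      // --- block 3: latent X_ij | rest (random-walk Metropolis) ---
      for (arma::uword i = 0; i < N; ++i) {
        const arma::uword s = set_start(i), ni = set_size(i);
        double lse_old = include_disease ? lse_set(eta, s, ni) : 0.0;
        for (arma::uword j = 0; j < ni; ++j) {
          const arma::uword r = s + j;
          arma::vec x_old = X.row(r).t();
          arma::vec x_new = x_old + step_x * (prop_sd_x % rnorm_vec(P));
          arma::vec mi = M.row(i).t();
          double lr = 0.0;
          for (arma::uword p = 0; p < P; ++p) {
            double wo = W(r, p);
            lr += (std::pow(wo - x_old(p), 2) - std::pow(wo - x_new(p), 2)) /
                  (2.0 * sigma2(p));
          }
          arma::vec dn = x_new - mi, dl = x_old - mi;
          lr += 0.5 * arma::as_scalar(dl.t() * invVW * dl) -
                0.5 * arma::as_scalar(dn.t() * invVW * dn);
          double eta_new = eta(r) + arma::dot(x_new - x_old, beta);
          double lse_new = lse_old;
          if (include_disease) {
            double eta_save = eta(r);
            eta(r) = eta_new;
            lse_new = lse_set(eta, s, ni);
            eta(r) = eta_save;
            lr += (j == 0 ? (eta_new - eta(r)) : 0.0) - (lse_new - lse_old);
          }
          if (std::log(R::unif_rand()) < lr) {
            X.row(r) = x_new.t();
            eta(r) = eta_new;
            lse_old = lse_new;
            acc_x_it += 1.0;
          }
        }
      }
      acc_x_it /= double(n);
    }

    // --- block 4: (beta, delta) | rest, adaptive random-walk Metropolis ---
    for (int rep = 0; rep < n_bd_updates; ++rep) {
      arma::vec beta_new = beta + step_b * (bd_sd.head(P) % rnorm_vec(P));
      arma::vec delta_new = delta;
      if (K > 0) delta_new += step_b * (bd_sd.tail(K) % rnorm_vec(K));
      arma::vec eta_new = Xcur * beta_new;
      if (K > 0) eta_new += Z * delta_new;
      double lr = include_disease
                      ? log_disease_eta(eta_new, set_start, set_size) -
                            log_disease_eta(eta, set_start, set_size)
                      : 0.0;
      lr += 0.5 * prior_b_prec *
            (arma::dot(beta, beta) - arma::dot(beta_new, beta_new));
      if (K > 0)
        lr += 0.5 * prior_d_prec *
              (arma::dot(delta, delta) - arma::dot(delta_new, delta_new));
      if (std::log(R::unif_rand()) < lr) {
        beta = beta_new;
        delta = delta_new;
        eta = eta_new;
        acc_b_it += 1.0;
      }
    }
    acc_b_it /= double(n_bd_updates);

    // --- adaptation (burn-in only; frozen afterwards) ---
    if (arma::uword(it) < n_adapt) {
      double g = std::pow(double(it + 1), -0.6);
      if (!naive) step_x *= std::exp(g * (acc_x_it - 0.35));
      step_b *= std::exp(g * (acc_b_it - 0.35));
      // Welford update of (beta, delta) moments for the diagonal proposal
      bd_n += 1;
      arma::vec bd(D);
      bd.head(P) = beta;
      if (K > 0) bd.tail(K) = delta;
      arma::vec d1 = bd - bd_mean;
      bd_mean += d1 / double(bd_n);
      bd_m2 += d1 % (bd - bd_mean);
      if (bd_n >= 100) {
        arma::vec sd = arma::sqrt(bd_m2 / double(bd_n - 1));
        bd_sd = arma::clamp(sd, 1e-3, arma::datum::inf);
      }
    } else {
      acc_x_sum += acc_x_it;
      acc_b_sum += acc_b_it;
      n_post += 1;
    }

    // --- bookkeeping: draws and full log-posterior recomputation ---
    draws_beta.row(it) = beta.t();
    if (K > 0) draws_delta.row(it) = delta.t();
    double lp = include_disease ? log_disease_eta(eta, set_start, set_size) : 0.0;
    for (arma::uword p = 0; p < P; ++p)
      lp += -0.5 * beta(p) * beta(p) / beta_var -
            0.5 * std::log(2.0 * M_PI * beta_var);
    for (arma::uword k = 0; k < K; ++k)
      lp += -0.5 * delta(k) * delta(k) / delta_var -
            0.5 * std::log(2.0 * M_PI * delta_var);
    if (!naive) {
      for (arma::uword p = 0; p < P; ++p) {
        double s2 = sigma2(p);
        for (arma::uword r = 0; r < n; ++r)
          lp += -0.5 * std::pow(W(r, p) - X(r, p), 2) / s2 -
                0.5 * std::log(2.0 * M_PI * s2);
      }
      for (arma::uword i = 0; i < N; ++i) {
        lp += log_dmvnorm_prec(M.row(i).t(), mu, invVB, ldVBinv);
        for (arma::uword j = 0; j < set_size(i); ++j)
          lp += log_dmvnorm_prec(X.row(set_start(i) + j).t(), M.row(i).t(),
                                 invVW, ldVWinv);
      }
      lp += log_dwishart(invVW, wish_R, wish_df) +
            log_dwishart(invVB, wish_R, wish_df);
      draws_vw.row(it) = arma::vectorise(VW).t();
      draws_vb.row(it) = arma::vectorise(VB).t();
    }
    lp_trace(it) = lp;
  }

  return List::create(
      _["beta"] = draws_beta, _["delta"] = draws_delta,
      _["vw"] = draws_vw, _["vb"] = draws_vb, _["lp"] = lp_trace,
      _["accept_x"] = n_post ? acc_x_sum / double(n_post) : NA_REAL,
      _["accept_beta"] = n_post ? acc_b_sum / double(n_post) : NA_REAL,
      _["step_x"] = step_x, _["step_b"] = step_b,
      _["final"] = List::create(_["X"] = X, _["M"] = M, _["VW"] = VW,
                                _["VB"] = VB, _["beta"] = beta,
                                _["delta"] = delta,
                                _["lp"] = lp_trace(n_iter - 1)));
}
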