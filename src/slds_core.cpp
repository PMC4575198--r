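// Core linear-Gaussian recursions for the switching linear dynamical system:
// Kalman filter (Joseph-form updates), RTS smoother, forward-filter
// backward-sampling of the latent path, discrete backward-message sampling of
// the state sequence, and per-state regression sufficient statistics.
//
// Conventions shared with the R layer:
//   * psi is T x d (rows are frames), positions in micrometres.
//   * Transition i (frame i -> i+1) is governed by the i-th slice of the
//     per-transition parameter arrays (source-frame indexing), i = 1..T-1.
//   * R may vary per frame (slice i applies to frame i's measurement).
//   * init_mean / init_cov parameterize the prior of r_1; the filter updates
//     with psi_1 and the reported log-likelihood sums the one-step predictive
//     densities of frames 2..T (frame 1 is treated as initialization).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double COV_JITTER = 1e-14;

static inline arma::mat symm(const arma::mat& A) {
  return 0.5 * (A + A.t());
}

// [[Rcpp::export]]
List cpp_kalman_filter(const arma::mat& psi,
                       const arma::mat& mu_seq,
                       const arma::cube& F_seq,
                       const arma::cube& Q_seq,
                       const arma::cube& R_seq,
                       const arma::vec& init_mean,
                       const arma::mat& init_cov) {
  const int T = psi.n_rows, d = psi.n_cols;
  arma::mat filt_mean(T, d), pred_state_mean(T, d), pred_obs_mean(T, d);
  arma::cube filt_cov(d, d, T), pred_state_cov(d, d, T), pred_obs_cov(d, d, T);
  const arma::mat Id = arma::eye(d, d);
  double loglik = 0.0;

  arma::vec mp = init_mean;
  arma::mat Pp = symm(init_cov);
  for (int i = 0; i < T; ++i) {
    pred_state_mean.row(i) = mp.t();
    pred_state_cov.slice(i) = Pp;
    arma::mat S = symm(Pp + R_seq.slice(i));
    S.diag() += COV_JITTER;
    pred_obs_mean.row(i) = mp.t();
    pred_obs_cov.slice(i) = S;
    arma::vec innov = psi.row(i).t() - mp;
    arma::mat Sinv = arma::inv_sympd(S);
    if (i > 0) {
      double ld, sgn;
      arma::log_det(ld, sgn, S);
      loglik += -0.5 * (d * std::log(2.0 * M_PI) + ld +
                        arma::as_scalar(innov.t() * Sinv * innov));
    }
    arma::mat K = Pp * Sinv;
    arma::vec mf = mp + K * innov;
    arma::mat IK = Id - K;
    arma::mat Pf = symm(IK * Pp * IK.t() + K * R_seq.slice(i) * K.t());
    filt_mean.row(i) = mf.t();
    filt_cov.slice(i) = Pf;
    if (i < T - 1) {
      const arma::mat& F = F_seq.slice(i);
      mp = mu_seq.row(i).t() + F * mf;
      Pp = symm(F * Pf * F.t() + Q_seq.slice(i));
    }
  }
  return List::create(_["filt_mean"] = filt_mean,
                      _["filt_cov"] = filt_cov,
                      _["pred_state_mean"] = pred_state_mean,
                      _["pred_state_cov"] = pred_state_cov,
                      _["pred_obs_mean"] = pred_obs_mean,
                      _["pred_obs_cov"] = pred_obs_cov,
                      _["loglik"] = loglik);
}

// Hand-coded 2x2 filter log-likelihood (symmetric matrices stored as
// (a11, a12, a22) triples); avoids small-matrix library overhead in the
// innermost MLE loop.
static double kalman_loglik_2d(const arma::mat& psi,
                               const arma::vec& mu,
                               const arma::mat& F,
                               const arma::mat& Q,
                               const arma::mat& R,
                               const arma::vec& init_mean,
                               const arma::mat& init_cov) {
  const int T = psi.n_rows;
  const double f11 = F(0, 0), f12 = F(0, 1), f21 = F(1, 0), f22 = F(1, 1);
  const double q11 = Q(0, 0), q12 = Q(0, 1), q22 = Q(1, 1);
  const double r11 = R(0, 0), r12 = R(0, 1), r22 = R(1, 1);
  double mp1 = init_mean(0), mp2 = init_mean(1);
  double p11 = init_cov(0, 0), p12 = init_cov(0, 1), p22 = init_cov(1, 1);
  const double log2pi = std::log(2.0 * M_PI);
  double loglik = 0.0;
  for (int i = 0; i < T; ++i) {
    double s11 = p11 + r11 + COV_JITTER;
    double s12 = p12 + r12;
    double s22 = p22 + r22 + COV_JITTER;
    double det = s11 * s22 - s12 * s12;
    if (det <= 0.0 || !std::isfinite(det)) return -std::numeric_limits<double>::infinity();
    double i11 = s22 / det, i12 = -s12 / det, i22 = s11 / det;
    double v1 = psi(i, 0) - mp1, v2 = psi(i, 1) - mp2;
    if (i > 0) {
      double quad = v1 * (i11 * v1 + i12 * v2) + v2 * (i12 * v1 + i22 * v2);
      loglik += -0.5 * (2.0 * log2pi + std::log(det) + quad);
    }
    // gain K = P S^{-1}
    double k11 = p11 * i11 + p12 * i12, k12 = p11 * i12 + p12 * i22;
    double k21 = p12 * i11 + p22 * i12, k22 = p12 * i12 + p22 * i22;
    double mf1 = mp1 + k11 * v1 + k12 * v2;
    double mf2 = mp2 + k21 * v1 + k22 * v2;
    // Pf = P - K P (standard form; S symmetric PSD keeps this stable enough
    // for the likelihood path, and the jitter guards the inversion)
    double pf11 = p11 - (k11 * p11 + k12 * p12);
    double pf12 = p12 - (k11 * p12 + k12 * p22);
    double pf22 = p22 - (k21 * p12 + k22 * p22);
    pf12 = 0.5 * (pf12 + (p12 - (k21 * p11 + k22 * p12)));
    if (i < T - 1) {
      mp1 = mu(0) + f11 * mf1 + f12 * mf2;
      mp2 = mu(1) + f21 * mf1 + f22 * mf2;
      // Pp = F Pf F' + Q
      double a11 = f11 * pf11 + f12 * pf12, a12 = f11 * pf12 + f12 * pf22;
      double a21 = f21 * pf11 + f22 * pf12, a22 = f21 * pf12 + f22 * pf22;
      p11 = a11 * f11 + a12 * f12 + q11;
      p12 = a11 * f21 + a12 * f22 + q12;
      p22 = a21 * f21 + a22 * f22 + q22;
    }
  }
  return loglik;
}

// Log-likelihood only, constant parameters; fast path for MLE objective.
// [[Rcpp::export]]
double cpp_kalman_loglik_const(const arma::mat& psi,
                               const arma::vec& mu,
                               const arma::mat& F,
                               const arma::mat& Q,
                               const arma::mat& R,
                               const arma::vec& init_mean,
                               const arma::mat& init_cov) {
  const int T = psi.n_rows, d = psi.n_cols;
  if (d == 2)
    return kalman_loglik_2d(psi, mu, F, Q, R, init_mean, init_cov);
  const arma::mat Id = arma::eye(d, d);
  double loglik = 0.0;
  arma::vec mp = init_mean;
  arma::mat Pp = symm(init_cov);
  for (int i = 0; i < T; ++i) {
    arma::mat S = symm(Pp + R);
    S.diag() += COV_JITTER;
    arma::vec innov = psi.row(i).t() - mp;
    arma::mat Sinv = arma::inv_sympd(S);
    if (i > 0) {
      double ld, sgn;
      arma::log_det(ld, sgn, S);
      loglik += -0.5 * (d * std::log(2.0 * M_PI) + ld +
                        arma::as_scalar(innov.t() * Sinv * innov));
    }
    arma::mat K = Pp * Sinv;
    arma::vec mf = mp + K * innov;
    arma::mat IK = Id - K;
    arma::mat Pf = symm(IK * Pp * IK.t() + K * R * K.t());
    if (i < T - 1) {
      mp = mu + F * mf;
      Pp = symm(F * Pf * F.t() + Q);
    }
  }
  return loglik;
}

// [[Rcpp::export]]
List cpp_rts_smoother(const arma::mat& filt_mean,
                      const arma::cube& filt_cov,
                      const arma::mat& pred_state_mean,
                      const arma::cube& pred_state_cov,
                      const arma::cube& F_seq) {
  const int T = filt_mean.n_rows, d = filt_mean.n_cols;
  arma::mat sm_mean(T, d);
  arma::cube sm_cov(d, d, T);
  sm_mean.row(T - 1) = filt_mean.row(T - 1);
  sm_cov.slice(T - 1) = filt_cov.slice(T - 1);
  for (int i = T - 2; i >= 0; --i) {
    arma::mat Pp = pred_state_cov.slice(i + 1);
    Pp.diag() += COV_JITTER;
    arma::mat J = filt_cov.slice(i) * F_seq.slice(i).t() * arma::inv_sympd(Pp);
    sm_mean.row(i) = filt_mean.row(i) +
      (J * (sm_mean.row(i + 1) - pred_state_mean.row(i + 1)).t()).t();
    sm_cov.slice(i) = symm(filt_cov.slice(i) +
      J * (sm_cov.slice(i + 1) - pred_state_cov.slice(i + 1)) * J.t());
  }
  return List::create(_["mean"] = sm_mean, _["cov"] = sm_cov);
}

// Draw one latent path r_{1:T} | psi, theta, R.  Uses R's RNG so that
// set.seed() on the R side makes draws reproducible.
// [[Rcpp::export]]
arma::mat cpp_ffbs_path(const arma::mat& filt_mean,
                        const arma::cube& filt_cov,
                        const arma::mat& pred_state_mean,
                        const arma::cube& pred_state_cov,
                        const arma::cube& F_seq) {
  const int T = filt_mean.n_rows, d = filt_mean.n_cols;
  arma::mat path(T, d);
  // sample r_T from the filtered distribution
  {
    arma::mat P = filt_cov.slice(T - 1);
    P.diag() += COV_JITTER;
    arma::mat L = arma::chol(symm(P), "lower");
    arma::vec z(d);
    for (int j = 0; j < d; ++j) z(j) = R::norm_rand();
    path.row(T - 1) = filt_mean.row(T - 1) + (L * z).t();
  }
  for (int i = T - 2; i >= 0; --i) {
    arma::mat Pp = pred_state_cov.slice(i + 1);
    Pp.diag() += COV_JITTER;
    arma::mat J = filt_cov.slice(i) * F_seq.slice(i).t() * arma::inv_sympd(Pp);
    arma::vec m = filt_mean.row(i).t() +
      J * (path.row(i + 1) - pred_state_mean.row(i + 1)).t();
    arma::mat P = symm(filt_cov.slice(i) - J * pred_state_cov.slice(i + 1) * J.t());
    P.diag() += COV_JITTER;
    arma::mat L = arma::chol(P, "lower");
    arma::vec z(d);
    for (int j = 0; j < d; ++j) z(j) = R::norm_rand();
    path.row(i) = m.t() + (L * z).t();
  }
  return path;
}

static inline double logsumexp(const arma::vec& x) {
  double m = x.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(arma::accu(arma::exp(x - m)));
}

// Joint draw of z_{1:T} | r, theta, pi, beta by backward message passing and
// forward sampling.  z_i governs transition i -> i+1; z_1 is weighted by the
// global HDP weights beta; z_T carries no emission term.  Returns 1-based
// labels.
// [[Rcpp::export]]
arma::ivec cpp_sample_z(const arma::mat& r,
                        const arma::mat& mu_k,
                        const arma::cube& F_k,
                        const arma::cube& Sig_k,
                        const arma::mat& log_pi,
                        const arma::vec& log_beta) {
  const int T = r.n_rows, d = r.n_cols, K = mu_k.n_rows;
  const double c0 = -0.5 * d * std::log(2.0 * M_PI);
  // Emission log-likelihoods e(i,k) for i = 1..T-1 (0-based rows 0..T-2),
  // computed state-by-state on bulk residual matrices.
  const arma::mat r_src = r.rows(0, T - 2);
  const arma::mat r_dst = r.rows(1, T - 1);
  arma::mat e(T, K, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    arma::mat S = symm(Sig_k.slice(k));
    S.diag() += COV_JITTER;
    arma::mat L = arma::chol(S, "lower");
    arma::mat Linv = arma::inv(arma::trimatl(L));
    double logdet = 2.0 * arma::accu(arma::log(L.diag()));
    arma::mat resid = r_dst - r_src * F_k.slice(k).t();
    resid.each_row() -= mu_k.row(k);
    arma::mat w = resid * Linv.t();
    e.submat(0, k, T - 2, k) = c0 - 0.5 * logdet - 0.5 * arma::sum(w % w, 1);
  }
  // Backward messages b(i,k) = log p(r_{i+2:T} | z_i = k) (up to constants),
  // via max-shifted matrix-vector products with the transition matrix.
  const arma::mat Pi = arma::exp(log_pi);
  arma::mat b(T, K, arma::fill::zeros);
  for (int i = T - 2; i >= 0; --i) {
    arma::vec nxt = (e.row(i + 1) + b.row(i + 1)).t();
    double m = nxt.max();
    b.row(i) = (arma::log(Pi * arma::exp(nxt - m)) + m).t();
  }
  // Forward sampling with R's RNG.
  arma::ivec z(T);
  arma::vec lp = log_beta + e.row(0).t() + b.row(0).t();
  for (int i = 0; i < T; ++i) {
    if (i > 0) lp = log_pi.row(z(i - 1) - 1).t() + e.row(i).t() + b.row(i).t();
    arma::vec p = arma::exp(lp - lp.max());
    p /= arma::accu(p);
    double u = R::unif_rand(), acc = 0.0;
    int pick = K - 1;
    for (int k = 0; k < K; ++k) { acc += p(k); if (u <= acc) { pick = k; break; } }
    z(i) = pick + 1;
  }
  return z;
}

// Regression sufficient statistics per state for the conjugate MNIW update
// of the transition model r_{i+1} = [F mu] [r_i; 1] + eta, grouped by z_i.
// [[Rcpp::export]]
List cpp_state_suffstats(const arma::mat& r, const arma::ivec& z, const int K) {
  const int T = r.n_rows, d = r.n_cols, p = d + 1;
  arma::cube Sxx(p, p, K, arma::fill::zeros);
  arma::cube Sxy(p, d, K, arma::fill::zeros);
  arma::cube Syy(d, d, K, arma::fill::zeros);
  arma::ivec n(K, arma::fill::zeros);
  arma::vec x(p);
  x(d) = 1.0;
  for (int i = 0; i < T - 1; ++i) {
    int k = z(i) - 1;
    for (int j = 0; j < d; ++j) x(j) = r(i, j);
    arma::vec y = r.row(i + 1).t();
    Sxx.slice(k) += x * x.t();
    Sxy.slice(k) += x * y.t();
    Syy.slice(k) += y * y.t();
    n(k) += 1;
  }
  return List::create(_["n"] = n, _["Sxx"] = Sxx, _["Sxy"] = Sxy, _["Syy"] = Syy);
}

// Principal matrix exponential / logarithm helpers (dense, small d).
// [[Rcpp::export]]
arma::mat cpp_expmat(const arma::mat& M) {
  return arma::expmat(M);
}

// [[Rcpp::export]]
List cpp_logmat(const arma::mat& M) {
  arma::cx_mat L = arma::logmat(M);
  double imnorm = arma::norm(arma::imag(L), "fro");
  return List::create(_["real"] = arma::mat(arma::real(L)), _["imnorm"] = imnorm);
}
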