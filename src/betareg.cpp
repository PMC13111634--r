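// Beta regression (logit mean link, constant precision, maximum likelihood)
// fitted by Fisher scoring, following the standard mean/precision
// parameterisation: y ~ Beta(mu * phi, (1 - mu) * phi).
//
// Written as a dedicated small fitter because the covariate correction step
// of the DMR caller fits one model per CpG site over >10^4 sites and needs
// to be fast; validated against glmmTMB's beta family in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double beta_loglik(const vec& y, const mat& X, const vec& gamma,
                          double phi) {
  vec eta = X * gamma;
  vec mu = 1.0 / (1.0 + exp(-eta));
  double ll = 0;
  int n = y.n_elem;
  for (int i = 0; i < n; ++i) {
    double p = mu[i] * phi, q = (1.0 - mu[i]) * phi;
    ll += std::lgamma(phi) - std::lgamma(p) - std::lgamma(q) +
          (p - 1.0) * std::log(y[i]) + (q - 1.0) * std::log1p(-y[i]);
  }
  return ll;
}

// [[Rcpp::export(name = ".cpp_betareg_fit")]]
Rcpp::List cpp_betareg_fit(const arma::vec& y, const arma::mat& X,
                           int maxit = 100, double tol = 1e-8) {
  int n = y.n_elem, k = X.n_cols;
  // starting values: least squares on the logit scale
  vec ystar0 = log(y / (1.0 - y));
  vec gamma = solve(X.t() * X + 1e-8 * eye(k, k), X.t() * ystar0);
  vec eta = X * gamma;
  vec mu = 1.0 / (1.0 + exp(-eta));
  double rss = 0;
  {
    vec fitted_ls = X * gamma;
    vec mu0 = 1.0 / (1.0 + exp(-fitted_ls));
    vec res = y - mu0;
    rss = dot(res, res) / std::max(n - k, 1);
  }
  double vbar = std::max(rss, 1e-8);
  double mbar = mean(mu % (1.0 - mu));
  double phi = std::min(std::max(mbar / vbar - 1.0, 1.0), 1e6);
  double tau = std::log(phi);

  double ll = beta_loglik(y, X, gamma, phi);
  bool converged = false;

  for (int it = 0; it < maxit; ++it) {
    eta = X * gamma;
    mu = 1.0 / (1.0 + exp(-eta));
    mu = clamp(mu, 1e-10, 1.0 - 1e-10);
    phi = std::exp(tau);
    vec p = mu * phi, q = (1.0 - mu) * phi;
    vec ystar = log(y / (1.0 - y));
    vec mustar(n), psi1p(n), psi1q(n);
    for (int i = 0; i < n; ++i) {
      mustar[i] = R::digamma(p[i]) - R::digamma(q[i]);
      psi1p[i] = R::trigamma(p[i]);
      psi1q[i] = R::trigamma(q[i]);
    }
    vec T = mu % (1.0 - mu);  // d mu / d eta for the logit link
    // scores
    vec sg = phi * (X.t() * (T % (ystar - mustar)));
    double sphi = 0;
    for (int i = 0; i < n; ++i)
      sphi += mu[i] * (ystar[i] - mustar[i]) + std::log1p(-y[i]) -
              R::digamma(q[i]) + R::digamma(phi);
    double stau = sphi * phi;  // chain rule for tau = log phi
    // expected information
    vec w = phi * ((psi1p + psi1q) % T % T);
    mat Kgg = phi * (X.t() * (X.each_col() % w));
    vec cvec = phi * (psi1p % mu - psi1q % (1.0 - mu));
    vec Kgp = X.t() * (T % cvec);
    double tg_phi = R::trigamma(phi);
    double Kpp = 0;
    for (int i = 0; i < n; ++i)
      Kpp += psi1p[i] * mu[i] * mu[i] + psi1q[i] * (1.0 - mu[i]) * (1.0 - mu[i]);
    Kpp -= n * tg_phi;
    // assemble in (gamma, tau) coordinates
    mat K(k + 1, k + 1);
    K.submat(0, 0, k - 1, k - 1) = Kgg;
    K.submat(0, k, k - 1, k) = Kgp * phi;
    K.submat(k, 0, k, k - 1) = (Kgp * phi).t();
    K(k, k) = Kpp * phi * phi;
    vec score(k + 1);
    score.subvec(0, k - 1) = sg;
    score[k] = stau;
    vec step;
    if (!solve(step, K + 1e-8 * eye(k + 1, k + 1), score)) break;
    // step halving on the log-likelihood
    double t_step = 1.0;
    vec g_new; double tau_new, ll_new = -datum::inf;
    for (int h = 0; h < 30; ++h) {
      g_new = gamma + t_step * step.subvec(0, k - 1);
      tau_new = tau + t_step * step[k];
      if (tau_new > 20.0) tau_new = 20.0;
      ll_new = beta_loglik(y, X, g_new, std::exp(tau_new));
      if (std::isfinite(ll_new) && ll_new >= ll - 1e-10) break;
      t_step *= 0.5;
    }
    if (!std::isfinite(ll_new)) break;
    double delta = std::max(std::fabs(ll_new - ll),
                            max(abs(g_new - gamma)));
    gamma = g_new; tau = tau_new; ll = ll_new;
    if (delta < tol) { converged = true; break; }
  }
  phi = std::exp(tau);
  eta = X * gamma;
  mu = 1.0 / (1.0 + exp(-eta));
  return Rcpp::List::create(Rcpp::Named("coefficients") = gamma,
                            Rcpp::Named("phi") = phi,
                            Rcpp::Named("fitted") = mu,
                            Rcpp::Named("loglik") = ll,
                            Rcpp::Named("converged") = converged);
}
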