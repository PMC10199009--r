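// MCMC sampler for the Gaussian Leroux CAR regression
//   y = X beta + phi + eps,  eps ~ N(0, nu2 I)
//   phi ~ N(0, tau2 * Q(rho)^-1),  Q(rho) = rho (D - W) + (1 - rho) I
// Updates: beta conjugate Gaussian; phi single-site Gibbs; nu2, tau2
// conjugate inverse-gamma; rho random-walk Metropolis on [0,1] with
// reflection, step adapted during burn-in towards 30-50% acceptance.
// All randomness comes from R's RNG so set.seed() reproduces chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double quad_form_leroux(const arma::vec& phi, const arma::ivec& nb,
                               const arma::ivec& nb_start,
                               const arma::vec& degree, double rho) {
  // phi' Q phi with Q = rho (D - W) + (1 - rho) I
  int n = phi.n_elem;
  double cross = 0.0, diag = 0.0;
  for (int i = 0; i < n; i++) {
    double sum_nb = 0.0;
    for (int k = nb_start[i]; k < nb_start[i + 1]; k++)
      sum_nb += phi[nb[k]];
    cross += phi[i] * (degree[i] * phi[i] - sum_nb);
    diag += phi[i] * phi[i];
  }
  return rho * cross + (1.0 - rho) * diag;
}

static double logdet_leroux(const arma::vec& lambda, double rho) {
  // log|Q(rho)| via eigenvalues lambda of (D - W)
  double s = 0.0;
  for (arma::uword i = 0; i < lambda.n_elem; i++) {
    double e = rho * lambda[i] + (1.0 - rho);
    if (e <= 0.0) return -arma::datum::inf;
    s += std::log(e);
  }
  return s;
}

static double rinvgamma(double shape, double rate) {
  // R::rgamma takes shape and SCALE
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// [[Rcpp::export(name = ".car_leroux_mcmc")]]
List car_leroux_mcmc(const arma::vec& y, const arma::mat& X,
                     const arma::ivec& nb, const arma::ivec& nb_start,
                     const arma::vec& lambda,
                     int n_iter, int burn_in, int thin,
                     double beta_prior_var,
                     double nu2_shape, double nu2_scale,
                     double tau2_shape, double tau2_scale,
                     bool store_phi) {
  RNGScope scope;
  const int n = y.n_elem, p = X.n_cols;
  arma::vec degree(n);
  for (int i = 0; i < n; i++) degree[i] = nb_start[i + 1] - nb_start[i];

  const arma::mat XtX = X.t() * X;
  const int n_keep = (n_iter - burn_in) / thin;

  // initial values: OLS-ish beta, residual-based variances
  arma::vec beta = arma::solve(XtX + 1e-8 * arma::eye(p, p), X.t() * y);
  arma::vec phi(n, arma::fill::zeros);
  arma::vec resid = y - X * beta;
  double nu2 = arma::dot(resid, resid) / std::max(n - p, 1);
  if (nu2 <= 0) nu2 = 0.01;
  double tau2 = nu2;
  double rho = 0.5, rho_step = 0.05;
  int rho_acc = 0, rho_try = 0;

  arma::mat beta_out(n_keep, p);
  arma::mat phi_out(store_phi ? n_keep : 0, store_phi ? n : 0);
  arma::vec nu2_out(n_keep), tau2_out(n_keep), rho_out(n_keep);
  int total_acc = 0, total_try = 0;

  for (int t = 1; t <= n_iter; t++) {
    // --- beta | rest: N(mu, P^-1), P = XtX/nu2 + I/sb
    arma::mat P = XtX / nu2;
    P.diag() += 1.0 / beta_prior_var;
    arma::mat U = arma::chol(P);  // P = U'U
    arma::vec b = X.t() * (y - phi) / nu2;
    arma::vec mu = arma::solve(P, b);
    arma::vec z(p);
    for (int j = 0; j < p; j++) z[j] = norm_rand();
    beta = mu + arma::solve(arma::trimatu(U), z);

    // --- phi | rest: single-site Gibbs under the Leroux conditionals
    arma::vec fit = X * beta;
    for (int i = 0; i < n; i++) {
      double sum_nb = 0.0;
      for (int k = nb_start[i]; k < nb_start[i + 1]; k++)
        sum_nb += phi[nb[k]];
      double prior_prec = (rho * degree[i] + 1.0 - rho) / tau2;
      double post_prec = prior_prec + 1.0 / nu2;
      double post_mean = (rho * sum_nb / tau2 + (y[i] - fit[i]) / nu2) /
                         post_prec;
      phi[i] = post_mean + norm_rand() / std::sqrt(post_prec);
    }
    phi -= arma::mean(phi);  // centre for identifiability with the intercept

    // --- nu2 | rest
    resid = y - fit - phi;
    nu2 = rinvgamma(nu2_shape + 0.5 * n,
                    nu2_scale + 0.5 * arma::dot(resid, resid));

    // --- tau2 | rest
    double quad = quad_form_leroux(phi, nb, nb_start, degree, rho);
    tau2 = rinvgamma(tau2_shape + 0.5 * n, tau2_scale + 0.5 * quad);

    // --- rho | rest: reflecting random-walk Metropolis, Uniform(0,1) prior
    double prop = rho + rho_step * norm_rand();
    while (prop < 0.0 || prop > 1.0) {
      if (prop < 0.0) prop = -prop;
      if (prop > 1.0) prop = 2.0 - prop;
    }
    double quad_prop = quad_form_leroux(phi, nb, nb_start, degree, prop);
    double log_acc = 0.5 * (logdet_leroux(lambda, prop) -
                            logdet_leroux(lambda, rho)) -
                     (quad_prop - quad) / (2.0 * tau2);
    rho_try++; total_try++;
    if (std::log(unif_rand()) < log_acc) {
      rho = prop;
      rho_acc++; total_acc++;
    }
    if (t <= burn_in && t % 100 == 0) {
      double rate = (double)rho_acc / rho_try;
      if (rate < 0.3) rho_step = std::max(rho_step * 0.8, 1e-4);
      else if (rate > 0.5) rho_step = std::min(rho_step * 1.2, 1.0);
      rho_acc = 0; rho_try = 0;
    }

    if (t > burn_in && (t - burn_in) % thin == 0) {
      int k = (t - burn_in) / thin - 1;
      beta_out.row(k) = beta.t();
      if (store_phi) phi_out.row(k) = phi.t();
      nu2_out[k] = nu2;
      tau2_out[k] = tau2;
      rho_out[k] = rho;
    }
    if (t % 5000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["beta"] = beta_out, _["phi"] = phi_out,
    _["nu2"] = nu2_out, _["tau2"] = tau2_out, _["rho"] = rho_out,
    _["rho_accept_rate"] = total_try > 0 ? (double)total_acc / total_try : 0.0,
    _["rho_step"] = rho_step);
}
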