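#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Newton-Raphson maximisation of the Bernoulli log-likelihood
//   l(beta) = sum_i [ y_i eta_i - log(1 + exp(eta_i)) ],  eta = X beta.
// X must already contain the intercept column if one is wanted.
// Convergence: relative change in l below `eps`, at most `maxit` iterations.
// Returns the observed-information covariance at the optimum; `ok = false`
// signals a numerically singular information matrix (rank deficiency).
// [[Rcpp::export]]
Rcpp::List logit_newton_cpp(const arma::mat& X, const arma::vec& y,
                            const arma::vec& init, double eps, int maxit) {
  const uword p = X.n_cols;
  vec beta = init;
  double ll = -datum::inf, ll_old = -datum::inf;
  bool conv = false, ok = true;
  int iter = 0;

  for (iter = 1; iter <= maxit; ++iter) {
    vec eta = X * beta;
    // log(1+exp(eta)) computed stably as max(eta,0) + log1p(exp(-|eta|))
    vec lse = eta;
    lse.transform([](double e) {
      return (e > 0 ? e : 0.0) + std::log1p(std::exp(-std::fabs(e)));
    });
    ll = dot(y, eta) - accu(lse);
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w  = mu % (1.0 - mu);
    mat H  = X.t() * (X.each_col() % w);
    vec g  = X.t() * (y - mu);
    vec step;
    if (!solve(step, H, g, solve_opts::no_approx)) { ok = false; break; }
    beta += step;
    if (std::isfinite(ll) && std::fabs(ll - ll_old) < eps * (std::fabs(ll) + eps)) {
      conv = true;
      break;
    }
    ll_old = ll;
  }

  // observed information and log-likelihood at the returned beta
  vec eta = X * beta;
  vec lse = eta;
  lse.transform([](double e) {
    return (e > 0 ? e : 0.0) + std::log1p(std::exp(-std::fabs(e)));
  });
  ll = dot(y, eta) - accu(lse);
  vec mu = 1.0 / (1.0 + exp(-eta));
  vec w  = mu % (1.0 - mu);
  mat H  = X.t() * (X.each_col() % w);
  mat cov(p, p, fill::value(datum::nan));
  vec se(p, fill::value(datum::nan));
  mat Hinv;
  if (ok && solve(Hinv, H, eye(p, p), solve_opts::no_approx)) {
    cov = Hinv;
    se  = sqrt(cov.diag());
  } else {
    ok = false;
  }

  return Rcpp::List::create(
    Rcpp::Named("coefficients") = beta,
    Rcpp::Named("se")           = se,
    Rcpp::Named("cov")          = cov,
    Rcpp::Named("loglik")       = ll,
    Rcpp::Named("converged")    = conv && ok,
    Rcpp::Named("singular")     = !ok,
    Rcpp::Named("iter")         = iter);
}
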