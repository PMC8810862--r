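// Ridge-penalized logistic regression (Newton with step halving) and a
// Mann-Whitney AUC kernel. These sit in the hot loop of the SFFS /
// cross-validation search (~1e5 fits per run), hence compiled code.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double plog_lik(const vec &eta, const vec &y, const vec &beta,
                       double lambda) {
  // log-likelihood - lambda/2 * ||beta||^2 (intercept unpenalized),
  // computed stably: ll = sum(y*eta - log(1 + exp(eta)))
  vec soft = eta;
  for (uword i = 0; i < eta.n_elem; ++i) {
    double e = eta[i];
    soft[i] = (e > 0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
  }
  return dot(y, eta) - accu(soft) - 0.5 * lambda * dot(beta, beta);
}

struct FitResult {
  vec coef;        // intercept first
  bool converged;
  int iterations;
};

static FitResult ridge_logit_core(const mat &X, const vec &y, double lambda,
                                  int max_iter, double tol) {
  const uword n = X.n_rows, p = X.n_cols;
  mat Z(n, p + 1);
  Z.col(0).ones();
  if (p > 0) Z.cols(1, p) = X;

  vec beta(p + 1, fill::zeros);
  double ybar = mean(y);
  ybar = std::min(std::max(ybar, 1e-12), 1.0 - 1e-12);
  beta[0] = std::log(ybar / (1.0 - ybar));

  vec eta = Z * beta;
  double obj = plog_lik(eta, y, p > 0 ? vec(beta.subvec(1, p)) : vec(zeros<vec>(0)), lambda);

  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    vec mu = 1.0 / (1.0 + exp(-eta));
    mu = clamp(mu, 1e-12, 1.0 - 1e-12);
    vec w = mu % (1.0 - mu);
    vec grad = Z.t() * (y - mu);
    if (p > 0) grad.subvec(1, p) -= lambda * beta.subvec(1, p);

    mat H = Z.t() * (Z.each_col() % w);
    for (uword j = 1; j <= p; ++j) H(j, j) += lambda;
    // tiny jitter keeps the intercept row invertible in degenerate cases
    H(0, 0) += 1e-12;

    vec step;
    bool ok = solve(step, H, grad, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) break;

    double t = 1.0;
    vec beta_new;
    double obj_new = obj;
    bool improved = false;
    for (int h = 0; h < 40; ++h) {
      beta_new = beta + t * step;
      vec eta_new = Z * beta_new;
      obj_new = plog_lik(eta_new, y,
                         p > 0 ? vec(beta_new.subvec(1, p)) : vec(zeros<vec>(0)),
                         lambda);
      if (std::isfinite(obj_new) && obj_new >= obj - 1e-14) {
        improved = true;
        eta = eta_new;
        break;
      }
      t *= 0.5;
    }
    if (!improved) break;
    beta = beta_new;
    double delta = std::abs(obj_new - obj);
    obj = obj_new;
    if (delta < tol * (std::abs(obj) + 0.1) &&
        norm(grad, "inf") < 1e-5 * (1.0 + static_cast<double>(n))) {
      converged = true;
      break;
    }
  }
  FitResult res;
  res.coef = beta;
  res.converged = converged;
  res.iterations = iter;
  return res;
}

// [[Rcpp::export(name = ".ridge_logit_cpp")]]
Rcpp::List ridge_logit_cpp(const arma::mat &X, const arma::vec &y,
                           double lambda, int max_iter, double tol) {
  FitResult r = ridge_logit_core(X, y, lambda, max_iter, tol);
  return Rcpp::List::create(
      Rcpp::Named("coef") = r.coef,
      Rcpp::Named("converged") = r.converged,
      Rcpp::Named("iterations") = r.iterations);
}

static double auc_core(const vec &s, const vec &y) {
  const uword n = s.n_elem;
  uvec ord = sort_index(s);
  vec r(n);
  uword i = 0;
  while (i < n) {
    uword j = i;
    while (j + 1 < n && s[ord[j + 1]] == s[ord[i]]) ++j;
    double avg = (static_cast<double>(i) + static_cast<double>(j)) / 2.0 + 1.0;
    for (uword k = i; k <= j; ++k) r[ord[k]] = avg;
    i = j + 1;
  }
  double n1 = accu(y), n0 = static_cast<double>(n) - n1;
  if (n1 == 0 || n0 == 0) return NA_REAL;
  double rsum = dot(r, y);
  return (rsum - n1 * (n1 + 1) / 2.0) / (n1 * n0);
}

// [[Rcpp::export(name = ".mw_auc_cpp")]]
double mw_auc_cpp(const arma::vec &scores, const arma::vec &y) {
  return auc_core(scores, y);
}

// Fit a ridge-logistic model on the given (0-based) column subset of X and
// return the training AUC of its linear scores: the SFFS selection criterion.
// [[Rcpp::export(name = ".logit_subset_auc_cpp")]]
double logit_subset_auc_cpp(const arma::mat &X, const arma::vec &y,
                            const arma::uvec &idx, double lambda,
                            int max_iter, double tol) {
  mat Xs = X.cols(idx);
  FitResult r = ridge_logit_core(Xs, y, lambda, max_iter, tol);
  vec eta = r.coef[0] + Xs * r.coef.subvec(1, Xs.n_cols);
  return auc_core(eta, y);
}
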