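// Fast IRLS deviance-explained engine for the hierarchical-partitioning and
// trait-tree randomization tests, which need many thousands of small GLM fits
// (all 2^k predictor subsets x all response permutations).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int FAM_GAUSSIAN = 0;
static const int FAM_POISSON  = 1;
static const int FAM_BINOMIAL = 2;

// y is the response (for binomial: the observed proportion), w the prior
// weight (for binomial: the number of trials; otherwise 1).
static double deviance(const vec &y, const vec &mu, const vec &w, int family) {
  double d = 0.0;
  const uword n = y.n_elem;
  switch (family) {
  case FAM_GAUSSIAN:
    for (uword i = 0; i < n; ++i) {
      double r = y[i] - mu[i];
      d += w[i] * r * r;
    }
    break;
  case FAM_POISSON:
    for (uword i = 0; i < n; ++i) {
      double t = (y[i] > 0.0) ? y[i] * std::log(y[i] / mu[i]) : 0.0;
      d += 2.0 * w[i] * (t - (y[i] - mu[i]));
    }
    break;
  case FAM_BINOMIAL:
    for (uword i = 0; i < n; ++i) {
      double t = 0.0;
      if (y[i] > 0.0)       t += y[i] * std::log(y[i] / mu[i]);
      if (y[i] < 1.0)       t += (1.0 - y[i]) * std::log((1.0 - y[i]) / (1.0 - mu[i]));
      d += 2.0 * w[i] * t;
    }
    break;
  }
  return d;
}

static vec linkinv(const vec &eta, int family) {
  switch (family) {
  case FAM_POISSON:  return exp(eta);
  case FAM_BINOMIAL: return 1.0 / (1.0 + exp(-eta));
  default:           return eta;
  }
}

// Fit one GLM by IRLS and return the residual deviance.
static double fit_deviance(const mat &X, const vec &y, const vec &w, int family) {
  const uword n = y.n_elem;
  if (family == FAM_GAUSSIAN) {
    mat Xw = X.each_col() % sqrt(w);
    vec yw = y % sqrt(w);
    vec beta;
    if (!solve(beta, Xw.t() * Xw, Xw.t() * yw, solve_opts::likely_sympd + solve_opts::no_approx))
      beta = pinv(Xw.t() * Xw) * (Xw.t() * yw);
    vec mu = X * beta;
    return deviance(y, mu, w, family);
  }

  vec eta(n);
  if (family == FAM_POISSON) {
    for (uword i = 0; i < n; ++i) eta[i] = std::log(std::max(y[i], 0.0) + 0.1);
  } else {
    for (uword i = 0; i < n; ++i) {
      double p = (w[i] * y[i] + 0.5) / (w[i] + 1.0);
      eta[i] = std::log(p / (1.0 - p));
    }
  }
  vec mu = linkinv(eta, family);
  double dev = deviance(y, mu, w, family);

  for (int iter = 0; iter < 60; ++iter) {
    vec vmu(n), z(n), wirls(n);
    if (family == FAM_POISSON) {
      for (uword i = 0; i < n; ++i) {
        double m = std::max(mu[i], 1e-10);
        z[i] = eta[i] + (y[i] - m) / m;
        wirls[i] = w[i] * m;
      }
    } else {
      for (uword i = 0; i < n; ++i) {
        double m = std::min(std::max(mu[i], 1e-10), 1.0 - 1e-10);
        double v = m * (1.0 - m);
        z[i] = eta[i] + (y[i] - m) / v;
        wirls[i] = w[i] * v;
      }
    }
    mat Xw = X.each_col() % sqrt(wirls);
    vec zw = z % sqrt(wirls);
    vec beta;
    if (!solve(beta, Xw.t() * Xw, Xw.t() * zw, solve_opts::likely_sympd + solve_opts::no_approx))
      beta = pinv(Xw.t() * Xw) * (Xw.t() * zw);
    eta = clamp(X * beta, -30.0, 30.0);
    mu = linkinv(eta, family);
    double dev_new = deviance(y, mu, w, family);
    if (std::abs(dev - dev_new) < 1e-9 * (std::abs(dev_new) + 0.1)) { dev = dev_new; break; }
    dev = dev_new;
  }
  return dev;
}

//' @noRd
// [[Rcpp::export]]
arma::mat cpp_gof_matrix(const arma::mat &X, Rcpp::List subsets,
                         const arma::mat &Y, const arma::mat &W, int family) {
  const uword n_resp = Y.n_cols;
  const uword n_sub = subsets.size();
  mat out(n_resp, n_sub, fill::zeros);
  mat ones_col(X.n_rows, 1, fill::ones);

  // pre-extract design matrices (intercept + subset columns)
  std::vector<mat> designs(n_sub);
  for (uword s = 0; s < n_sub; ++s) {
    Rcpp::IntegerVector idx = subsets[s];
    mat Xs(X.n_rows, 1 + idx.size());
    Xs.col(0).ones();
    for (int j = 0; j < idx.size(); ++j) Xs.col(j + 1) = X.col(idx[j]);
    designs[s] = Xs;
  }

  for (uword r = 0; r < n_resp; ++r) {
    vec y = Y.col(r);
    vec w = (W.n_cols == n_resp) ? vec(W.col(r)) : vec(W.col(0));
    double d0 = fit_deviance(ones_col, y, w, family);
    for (uword s = 0; s < n_sub; ++s) {
      if (designs[s].n_cols == 1) { out(r, s) = 0.0; continue; }
      if (d0 <= 1e-12) { out(r, s) = 0.0; continue; }
      double d = fit_deviance(designs[s], y, w, family);
      double g = 1.0 - d / d0;
      if (g < 0.0) g = 0.0;
      if (g > 1.0) g = 1.0;
      out(r, s) = g;
    }
  }
  return out;
}
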