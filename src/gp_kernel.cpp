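// Gaussian-process core: composite kernel (ARD squared-exponential +
// linear + bias + iid noise), negative log marginal likelihood with
// analytic gradient, and exact predictive equations. All hyperparameters
// are passed on the log scale:
//   theta = (log sf2, log ell_1..ell_d, log sl2, log sb2, log sn2)
// so the gradient returned is with respect to the log-parameters.
//
// The squared-distance matrices depend only on the covariates, which are
// shared across every vertex of a fold; .gp_precompute builds them once
// and the *_pre entry points reuse them across vertices and optimizer
// iterations.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// per-dimension squared differences (a_i - a_k)^2, unscaled
static cube sqdist_cube(const mat& X) {
  const uword n = X.n_rows, d = X.n_cols;
  cube D(n, n, d);
  for (uword j = 0; j < d; ++j) {
    vec a = X.col(j);
    D.slice(j) = repmat(square(a), 1, n) + repmat(square(a).t(), n, 1) -
                 2.0 * a * a.t();
  }
  return D;
}

// [[Rcpp::export(name = ".gp_precompute")]]
Rcpp::List gp_precompute(const arma::mat& X) {
  return Rcpp::List::create(Rcpp::Named("D") = sqdist_cube(X),
                            Rcpp::Named("XXt") = mat(X * X.t()),
                            Rcpp::Named("d") = (int)X.n_cols,
                            Rcpp::Named("n") = (int)X.n_rows);
}

// K(X1, X2) without the noise term.
static mat cross_kernel(const mat& X1, const mat& X2, const vec& theta) {
  const uword d = X1.n_cols;
  const double sf2 = std::exp(theta(0));
  const double sl2 = std::exp(theta(d + 1));
  const double sb2 = std::exp(theta(d + 2));
  mat Q(X1.n_rows, X2.n_rows, fill::zeros);
  for (uword j = 0; j < d; ++j) {
    const double inv_ell2 = std::exp(-2.0 * theta(1 + j));
    vec a = X1.col(j), b = X2.col(j);
    Q += inv_ell2 * (repmat(square(a), 1, X2.n_rows) +
                     repmat(square(b).t(), X1.n_rows, 1) -
                     2.0 * a * b.t());
  }
  return sf2 * exp(-0.5 * Q) + sl2 * (X1 * X2.t()) + sb2;
}

// Cholesky of Kbase + sn2 I + jitter, escalating jitter x10 up to
// max_escal times when the factorization fails.
static bool chol_with_jitter(const mat& Kbase, double sn2, double jitter_rel,
                             int max_escal, mat& L, double& jitter_used) {
  const uword n = Kbase.n_rows;
  const double mean_diag = trace(Kbase) / n + sn2;
  double jit = jitter_rel * mean_diag;
  for (int a = 0; a <= max_escal; ++a) {
    mat Ktry = Kbase;
    Ktry.diag() += sn2 + jit;
    if (chol(L, Ktry, "lower")) { jitter_used = jit; return true; }
    jit *= 10.0;
  }
  return false;
}

static Rcpp::List nlml_grad_core(const vec& theta, const cube& D,
                                 const mat& XXt, const vec& y,
                                 double jitter_rel, int max_escal,
                                 bool want_grad) {
  const uword n = y.n_elem, d = D.n_slices;
  const double sf2 = std::exp(theta(0));
  const double sl2 = std::exp(theta(d + 1));
  const double sb2 = std::exp(theta(d + 2));
  const double sn2 = std::exp(theta(d + 3));

  mat Q(n, n, fill::zeros);
  for (uword j = 0; j < d; ++j)
    Q += std::exp(-2.0 * theta(1 + j)) * D.slice(j);
  mat R = sf2 * exp(-0.5 * Q);
  mat Kbase = R + sl2 * XXt + sb2;

  mat L;
  double jit = 0.0;
  if (!chol_with_jitter(Kbase, sn2, jitter_rel, max_escal, L, jit))
    return Rcpp::List::create(Rcpp::Named("ok") = false);

  vec alpha = solve(trimatu(L.t()), solve(trimatl(L), y));
  double nlml = 0.5 * dot(y, alpha) + sum(log(L.diag())) + 0.5 * n * LOG2PI;

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("ok") = true, Rcpp::Named("nlml") = nlml,
      Rcpp::Named("jitter") = jit);
  if (!want_grad) return out;

  // W = K^{-1} - alpha alpha'; grad_j = 0.5 * sum(W % dK/dtheta_j)
  mat Linv = inv(trimatl(L));
  mat W = Linv.t() * Linv;           // K^{-1} from the existing factor
  W -= alpha * alpha.t();
  vec grad(d + 4);
  grad(0) = 0.5 * accu(W % R);                       // d/d log sf2
  for (uword j = 0; j < d; ++j)                      // d/d log ell_j
    grad(1 + j) = 0.5 * std::exp(-2.0 * theta(1 + j)) *
                  accu(W % R % D.slice(j));
  grad(d + 1) = 0.5 * sl2 * accu(W % XXt);           // d/d log sl2
  grad(d + 2) = 0.5 * sb2 * accu(W);                 // d/d log sb2
  grad(d + 3) = 0.5 * sn2 * trace(W);                // d/d log sn2
  out["grad"] = Rcpp::NumericVector(grad.begin(), grad.end());
  return out;
}

// [[Rcpp::export(name = ".gp_nlml_grad")]]
Rcpp::List gp_nlml_grad(const arma::vec& theta, const arma::mat& X,
                        const arma::vec& y, double jitter_rel = 1e-6,
                        int max_escal = 3, bool want_grad = true) {
  return nlml_grad_core(theta, sqdist_cube(X), X * X.t(), y, jitter_rel,
                        max_escal, want_grad);
}

// [[Rcpp::export(name = ".gp_nlml_grad_pre")]]
Rcpp::List gp_nlml_grad_pre(const arma::vec& theta, const arma::cube& D,
                            const arma::mat& XXt, const arma::vec& y,
                            double jitter_rel = 1e-6, int max_escal = 3,
                            bool want_grad = true) {
  return nlml_grad_core(theta, D, XXt, y, jitter_rel, max_escal, want_grad);
}

// Predictive mean and latent variance at Xs for a model with
// hyperparameters theta trained on (X, y); y is already centered.
// [[Rcpp::export(name = ".gp_predict")]]
Rcpp::List gp_predict(const arma::vec& theta, const arma::mat& X,
                      const arma::vec& y, const arma::mat& Xs,
                      double jitter_rel = 1e-6, int max_escal = 3) {
  const uword d = X.n_cols;
  const double sf2 = std::exp(theta(0));
  const double sl2 = std::exp(theta(d + 1));
  const double sb2 = std::exp(theta(d + 2));
  const double sn2 = std::exp(theta(d + 3));

  mat Kbase = cross_kernel(X, X, theta);
  mat L;
  double jit = 0.0;
  if (!chol_with_jitter(Kbase, sn2, jitter_rel, max_escal, L, jit))
    Rcpp::stop("covariance factorization failed after jitter escalation");

  mat Ks = cross_kernel(X, Xs, theta);
  vec alpha = solve(trimatu(L.t()), solve(trimatl(L), y));
  vec mean = Ks.t() * alpha;

  mat V = solve(trimatl(L), Ks);
  vec kss = sf2 + sl2 * sum(square(Xs), 1) + sb2;
  vec var_lat = kss - sum(square(V), 0).t();
  var_lat.transform([](double v) { return v < 0.0 ? 0.0 : v; });

  return Rcpp::List::create(Rcpp::Named("mean") = mean,
                            Rcpp::Named("var_latent") = var_lat,
                            Rcpp::Named("var_noise") = sn2,
                            Rcpp::Named("jitter") = jit);
}
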