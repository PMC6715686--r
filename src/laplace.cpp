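// Laplace approximation for the latent logit-binomial Gaussian process.
// Newton iteration and marginal-likelihood follow the standard GP treatment
// (Rasmussen & Williams alg. 3.1/3.2) with the binomial log-likelihood
//   log P(y_i | b_i, d_i) = y_i b_i - d_i log(1 + e^{b_i})  (+ log C(d_i, y_i)).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double softplus(double x) {
  return x > 30.0 ? x : std::log1p(std::exp(x));
}

static inline arma::vec logistic_vec(const arma::vec& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// log binomial likelihood without the choose() constant
static double loglik_bin(const arma::vec& y, const arma::vec& d, const arma::vec& f) {
  double ll = 0.0;
  for (arma::uword i = 0; i < f.n_elem; ++i)
    ll += y[i] * f[i] - d[i] * softplus(f[i]);
  return ll;
}

struct LaplaceResult {
  arma::vec f;      // posterior mode B-hat
  arma::vec alpha;  // K^{-1} f at mode (= grad log lik at mode)
  arma::vec sW;     // sqrt of W diagonal
  arma::mat L;      // lower Cholesky of I + sW K sW
  double logZ;      // Laplace log marginal likelihood (with choose constants)
  int iter;
  bool converged;
};

static LaplaceResult laplace_core(const arma::mat& K, const arma::vec& y,
                                  const arma::vec& d, int max_iter, double tol) {
  const arma::uword n = y.n_elem;
  arma::vec f(n, arma::fill::zeros), alpha(n, arma::fill::zeros);
  arma::vec sW(n), W(n), p(n), b(n);
  arma::mat L;
  double obj = loglik_bin(y, d, f); // psi at f = 0
  double lchoose_const = 0.0;
  for (arma::uword i = 0; i < n; ++i)
    lchoose_const += std::lgamma(d[i] + 1.0) - std::lgamma(y[i] + 1.0) -
                     std::lgamma(d[i] - y[i] + 1.0);
  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    p = logistic_vec(f);
    W = d % p % (1.0 - p);
    sW = arma::sqrt(W);
    arma::mat B = arma::eye(n, n) + (sW * sW.t()) % K;
    if (!arma::chol(L, B, "lower"))
      stop("Cholesky factorization failed in Laplace iteration (non-PSD covariance)");
    b = W % f + (y - d % p);
    arma::vec rhs = sW % (K * b);
    arma::vec v1 = arma::solve(arma::trimatl(L), rhs);
    arma::vec v2 = arma::solve(arma::trimatu(L.t()), v1);
    alpha = b - sW % v2;
    f = K * alpha;
    if (!f.is_finite())
      stop("Newton iteration diverged (non-finite posterior mode)");
    double obj_new = -0.5 * arma::dot(alpha, f) + loglik_bin(y, d, f);
    double denom = std::abs(obj_new);
    double rel = denom > 0 ? std::abs(obj_new - obj) / denom : std::abs(obj_new - obj);
    obj = obj_new;
    if (rel <= tol) { converged = true; break; }
  }
  // refresh W and L at the final mode
  p = logistic_vec(f);
  W = d % p % (1.0 - p);
  sW = arma::sqrt(W);
  arma::mat B = arma::eye(n, n) + (sW * sW.t()) % K;
  if (!arma::chol(L, B, "lower"))
    stop("Cholesky factorization failed at converged mode");
  double logZ = -0.5 * arma::dot(alpha, f) + loglik_bin(y, d, f) + lchoose_const -
                arma::sum(arma::log(L.diag()));
  LaplaceResult res{f, alpha, sW, L, logZ, it, converged};
  return res;
}

// [[Rcpp::export(name = ".laplace_fit_cpp")]]
List laplace_fit_cpp(const arma::mat& K, const arma::vec& y, const arma::vec& d,
                     int max_iter = 50, double tol = 1.4901161193847656e-08) {
  LaplaceResult r = laplace_core(K, y, d, max_iter, tol);
  arma::vec W = r.sW % r.sW;
  return List::create(_["b_hat"] = r.f, _["alpha"] = r.alpha, _["w_diag"] = W,
                      _["sW"] = r.sW, _["L"] = r.L, _["log_marginal"] = r.logZ,
                      _["iterations"] = r.iter, _["converged"] = r.converged);
}

// Posterior predictive mean/variance at new positions given a window fit.
// Kstar: n_window x n_new cross-covariances; kss: prior variances at new points.
// [[Rcpp::export(name = ".laplace_predict_cpp")]]
List laplace_predict_cpp(const arma::mat& K, const arma::vec& y, const arma::vec& d,
                         const arma::mat& Kstar, const arma::vec& kss,
                         int max_iter = 50, double tol = 1.4901161193847656e-08) {
  LaplaceResult r = laplace_core(K, y, d, max_iter, tol);
  arma::vec mu = Kstar.t() * r.alpha;
  arma::uword m = kss.n_elem;
  arma::vec s2(m);
  for (arma::uword j = 0; j < m; ++j) {
    arma::vec v = arma::solve(arma::trimatl(r.L), r.sW % Kstar.col(j));
    s2[j] = kss[j] - arma::dot(v, v);
  }
  return List::create(_["mu"] = mu, _["sigma2"] = s2,
                      _["log_marginal"] = r.logZ, _["converged"] = r.converged);
}

// Evaluate the Laplace log marginal over a grid of covariance parameters for
// one block. D2 is the squared-distance matrix; grid columns are (a, b, c, d).
// Rows must be ordered so equal (b, d) values are adjacent (kernel caching).
// [[Rcpp::export(name = ".grid_logz_cpp")]]
arma::vec grid_logz_cpp(const arma::mat& D2, const arma::vec& y, const arma::vec& d,
                        const arma::mat& grid, double jitter = 1e-6,
                        int max_iter = 50, double tol = 1.4901161193847656e-08) {
  const arma::uword G = grid.n_rows, n = y.n_elem;
  arma::vec out(G);
  double last_b = NA_REAL, last_dd = NA_REAL;
  arma::mat Eb(n, n), Ed(n, n);
  for (arma::uword g = 0; g < G; ++g) {
    double pa = grid(g, 0), pb = grid(g, 1), pc = grid(g, 2), pd = grid(g, 3);
    if (pb != last_b) { Eb = arma::exp(-D2 / (pb * pb)); last_b = pb; }
    if (pd != last_dd) { Ed = arma::exp(-D2 / (pd * pd)); last_dd = pd; }
    double ea = std::exp(pa), ec = std::exp(pc);
    arma::mat K = ea * Eb + ec * Ed;
    K.diag() += jitter * (ea + ec);
    LaplaceResult r = laplace_core(K, y, d, max_iter, tol);
    out[g] = r.logZ;
  }
  return out;
}
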