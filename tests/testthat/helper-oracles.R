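# Independent numerical oracles used to validate the Laplace / quadrature
# machinery. These deliberately avoid the package's code paths: plain
# stats::integrate and dense-grid integration.

# log of the exact 1-D marginal likelihood \int Bin(y; d, logistic(b)) N(b; 0, k) db
oracle_logz_1d <- function(y, d, k) {
  f <- function(b) dbinom(y, d, plogis(b)) * dnorm(b, 0, sqrt(k))
  log(integrate(f, -25, 25, rel.tol = 1e-12)$value)
}

# log marginal for n sites by dense-grid integration (n <= 3)
oracle_logz_grid <- function(pos, y, d, params, lim = 8, npt = 161) {
  K <- outer(pos, pos, function(a, b) ab_covariance(a, b, params))
  n <- length(pos)
  gr <- seq(-lim, lim, length.out = npt)
  h <- diff(gr)[1]
  Ki <- solve(K)
  ld <- as.numeric(determinant(2 * pi * K)$modulus)
  G <- as.matrix(expand.grid(rep(list(gr), n)))
  lik <- rep(1, nrow(G))
  for (i in seq_len(n)) lik <- lik * dbinom(y[i], d[i], plogis(G[, i]))
  q <- exp(-0.5 * rowSums((G %*% Ki) * G))
  log(sum(lik * q) * h^n) - 0.5 * ld
}

# exact 1-D Laplace approximation computed by direct optimization (checks the
# implementation, independent of its Newton/Cholesky path)
oracle_laplace_1d <- function(y, d, k) {
  psi <- function(b) dbinom(y, d, plogis(b), log = TRUE) - b^2 / (2 * k)
  opt <- optimize(psi, c(-15, 15), maximum = TRUE)
  bhat <- opt$maximum
  W <- d * plogis(bhat) * (1 - plogis(bhat))
  psi(bhat) - 0.5 * log(1 + k * W)
}

# outcome pmf by adaptive quadrature: P(Y = y' | mu, sigma2) for the ABC
# ("abc") or allele-mixture artifact ("artifact") model
oracle_pmf <- function(d, mu, sigma2, type = "abc", f = 2) {
  one <- function(yy) {
    g <- function(b) {
      p <- plogis(b)
      lik <- if (type == "abc") dbinom(yy, d, p)
             else 0.5 * dbinom(yy, d, p / f) + 0.5 * dbinom(yy, d, (1 - p) / f)
      lik * dnorm(b, mu, sqrt(sigma2))
    }
    integrate(g, mu - 12 * sqrt(sigma2) - 1, mu + 12 * sqrt(sigma2) + 1,
              rel.tol = 1e-10)$value
  }
  pmf <- vapply(0:d, one, numeric(1))
  pmf / sum(pmf)
}

oracle_tail_p <- function(pmf, k) sum(pmf[pmf <= pmf[k + 1] + 1e-12])

# GP posterior (mean, variance) at x* for <= 3 hSNPs by dense-grid
# integration over the latent values
oracle_gp_posterior <- function(pos, y, d, xstar, params, lim = 6, npt = 81) {
  allpos <- c(pos, xstar)
  Kall <- outer(allpos, allpos, function(a, b) ab_covariance(a, b, params))
  n <- length(pos)
  K <- Kall[1:n, 1:n, drop = FALSE]
  ks <- Kall[1:n, n + 1]
  kss <- Kall[n + 1, n + 1]
  Ki <- solve(K)
  gr <- seq(-lim, lim, length.out = npt)
  G <- as.matrix(expand.grid(rep(list(gr), n)))
  w <- rep(1, nrow(G))
  for (i in seq_len(n)) w <- w * dbinom(y[i], d[i], plogis(G[, i]))
  w <- w * exp(-0.5 * rowSums((G %*% Ki) * G))
  w <- w / sum(w)
  condmean <- as.numeric(G %*% (Ki %*% ks))
  condvar <- as.numeric(kss - t(ks) %*% Ki %*% ks)
  mu <- sum(w * condmean)
  list(mu = mu, sigma2 = condvar + sum(w * (condmean - mu)^2))
}

# exhaustive cutoff search for the FDR-tuned artifact alpha: evaluates every
# achievable p-value cutoff directly from per-outcome tail p-values
oracle_tune_alpha <- function(d, mu, sigma2, vaf, nt_i, na_i, theta, f) {
  g <- oracle_pmf(d, mu, sigma2, "artifact", f)
  ms <- mu_star(vaf, mu)
  h <- oracle_pmf(d, ms, sigma2, "abc")
  pvals <- vapply(0:d, function(k) oracle_tail_p(g, k), numeric(1))
  best <- 0
  for (al in sort(unique(pvals))) {
    rej <- pvals <= al + 1e-12
    a_actual <- sum(g[rej])
    pow <- sum(h[rej])
    fdr <- if (a_actual * na_i + pow * nt_i == 0) 0 else
      a_actual * na_i / (a_actual * na_i + pow * nt_i)
    if (fdr <= theta) best <- max(best, a_actual)
  }
  best
}
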