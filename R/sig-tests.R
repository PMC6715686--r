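# Genotyping tests on candidate sSNVs: allele-balance consistency (ABC) and
# the two amplification-artifact tests. All three share the same machinery:
# an outcome distribution P(Y = y' | AB posterior) over y' = 0..D obtained by
# marginalizing the binomial over the latent logit-AB with Gauss-Hermite
# quadrature, and a probability-ordered tail p-value.

# cache of Gauss-Hermite rules keyed by node count
.gh_env <- new.env(parent = emptyenv())
gh_rule <- function(n_nodes) {
  key <- as.character(n_nodes)
  if (is.null(.gh_env[[key]])) .gh_env[[key]] <- pracma::gaussHermite(n_nodes)
  .gh_env[[key]]
}

#' Orient the AB posterior toward the candidate's VAF
#'
#' The AB model tracks the amplification balance of one (arbitrary) allele,
#' but a somatic mutation can lie on either. `mu_star()` returns whichever
#' of `mu` and `-mu` has a logistic transform closest to the observed VAF;
#' ties go to `+mu`.
#'
#' @param vaf Observed variant allele fraction in `[0, 1]`.
#' @param mu Posterior mean of the latent logit-AB.
#' @return A scalar logit-scale value, `mu` or `-mu`.
#' @examples
#' mu_star(0.44, qlogis(0.89)) # -> -logit(0.89); 0.44 is nearer 0.11
#' @export
mu_star <- function(vaf, mu) {
  stopifnot(is.finite(vaf), is.finite(mu))
  if (abs(vaf - logistic(mu)) <= abs(vaf - logistic(-mu))) mu else -mu
}

# P(Y = y' | mu, sigma2) for y' = 0..d, marginalized over B ~ N(mu, sigma2).
# type "abc": success prob logistic(b).
# type "artifact": 1/2-1/2 allele mixture with success probs logistic(b)/f
#   and (1 - logistic(b))/f.
outcome_pmf <- function(d, mu, sigma2, type = c("abc", "artifact"), f = 2,
                        n_nodes = 128) {
  type <- match.arg(type)
  stopifnot(d >= 1, sigma2 >= 0)
  ys <- 0:d
  pmf_at <- function(b) { # vector over b; returns matrix (d+1) x length(b)
    p <- logistic(b)
    if (type == "abc") {
      vapply(p, function(pi) dbinom(ys, d, pi), numeric(d + 1))
    } else {
      vapply(p, function(pi) {
        0.5 * dbinom(ys, d, pi / f) + 0.5 * dbinom(ys, d, (1 - pi) / f)
      }, numeric(d + 1))
    }
  }
  if (sigma2 == 0) {
    pmf <- pmf_at(mu)[, 1]
  } else {
    gh <- gh_rule(n_nodes)
    b <- mu + sqrt(2 * sigma2) * gh$x
    w <- gh$w / sqrt(pi)
    pmf <- as.numeric(pmf_at(b) %*% w)
  }
  pmf / sum(pmf) # renormalize away quadrature error
}

# Probability-ordered tail p-value: sum of P(Y = y') over outcomes no more
# probable than the observed count (ties within tie_tol included).
tail_p_value <- function(pmf, k, tie_tol = 1e-12) {
  sum(pmf[pmf <= pmf[k + 1] + tie_tol])
}

#' Allele-balance consistency (ABC) test
#'
#' Tests whether the observed variant read count is consistent with the
#' locus's posterior allele balance. The null takes
#' `Y ~ Bin(D, logistic(B))` with `B ~ N(mu*, sigma2)` where `mu*` orients
#' the AB toward the observed VAF (see [mu_star()]); the outcome
#' distribution is computed by Gauss-Hermite quadrature and the p-value sums
#' all outcomes with probability no greater than the observed one. A true
#' heterozygous mutation should have p well above small cutoffs; sites whose
#' VAF cannot be explained by either allele's amplification balance get
#' small p.
#'
#' @param y Observed variant-supporting reads.
#' @param d Total depth (must be >= 1).
#' @param mu,sigma2 Posterior mean/variance of the latent logit-AB at the
#'   site (from [predict_ab()]).
#' @param n_nodes Gauss-Hermite node count (default 128).
#' @param keep_pmf Keep the full outcome pmf in the result?
#' @return A list of class `ab_test` with `p_value`, `mu_star`, `pmf`
#'   (optional).
#' @export
abc_test <- function(y, d, mu, sigma2, n_nodes = 128, keep_pmf = FALSE) {
  if (d < 1) abort("abc_test: depth must be >= 1 (untestable site)")
  stopifnot(y >= 0, y <= d, sigma2 >= 0)
  ms <- mu_star(y / d, mu)
  pmf <- outcome_pmf(d, ms, sigma2, "abc", n_nodes = n_nodes)
  structure(list(p_value = min(tail_p_value(pmf, y), 1), mu_star = ms, f = NA_real_,
                 pmf = if (keep_pmf) pmf else NULL), class = "ab_test")
}

#' Amplification-artifact tests
#'
#' Tests whether the observed variant read count is consistent with an
#' amplification artifact. The null is an equal mixture over the two
#' alleles: `Y ~ Bin(D, AB/f)` or `Y ~ Bin(D, (1-AB)/f)` with
#' `AB = logistic(B)`, `B ~ N(mu, sigma2)`. A pre-amplification
#' (single-stranded lesion) artifact occurs on half the carrier allele's
#' amplicons (`f = 2`); a first-round polymerase misincorporation on a
#' quarter (`f = 4`). No VAF orientation is needed: the mixture is symmetric
#' in `mu`. Small p means the artifact explanation is rejected.
#'
#' @inheritParams abc_test
#' @param f Artifact divisor: 2 (pre-amplification) or 4 (amplification).
#' @return A list of class `ab_test` with `p_value`, `f`, `pmf` (optional).
#' @export
artifact_test <- function(y, d, mu, sigma2, f = c(2, 4), n_nodes = 128,
                          keep_pmf = FALSE) {
  f <- match.arg(as.character(f[1]), c("2", "4"))
  f <- as.numeric(f)
  if (d < 1) abort("artifact_test: depth must be >= 1 (untestable site)")
  stopifnot(y >= 0, y <= d, sigma2 >= 0)
  pmf <- outcome_pmf(d, mu, sigma2, "artifact", f = f, n_nodes = n_nodes)
  structure(list(p_value = min(tail_p_value(pmf, y), 1), mu_star = NA_real_,
                 f = f, pmf = if (keep_pmf) pmf else NULL), class = "ab_test")
}

#' @export
print.ab_test <- function(x, ...) {
  lab <- if (is.na(x$f)) "ABC test" else sprintf("artifact test (f = %g)", x$f)
  cat(sprintf("%s: p = %.4g\n", lab, x$p_value))
  invisible(x)
}
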