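#' Covariance-function parameters for the allele-balance Gaussian process
#'
#' The spatial correlation of allele balance (AB) along the genome is modeled
#' by a sum of two radial basis functions,
#' \deqn{k(x_1, x_2) = \exp(a - (x_1-x_2)^2/b^2) + \exp(c - (x_1-x_2)^2/d^2),}
#' one capturing medium- to long-range correlation driven by MDA amplicon
#' size (log-amplitude `a`, length scale `b` in bp) and one capturing very
#' short-range effects such as shared reads between nearby loci
#' (log-amplitude `c`, length scale `d` in bp). By convention the short-range
#' term is the one with the smaller length scale; if `d > b` the two terms
#' are swapped.
#'
#' @param a,b,c,d Log-amplitudes (`a`, `c`, dimensionless) and length scales
#'   (`b`, `d`, base pairs) of the two kernel components.
#' @return An object of class `cov_params` (a named list).
#' @examples
#' cov_params(a = -1, b = 10000, c = -2, d = 150)
#' @export
cov_params <- function(a, b, c, d) {
  vals <- c(a = a, b = b, c = c, d = d)
  if (!all(is.finite(vals))) abort("covariance parameters must be finite")
  if (b <= 0 || d <= 0) abort("length scales b and d must be positive")
  if (d > b) { # enforce: (a, b) is the long-range component
    tmp <- c(a, b); a <- c; b <- d; c <- tmp[1]; d <- tmp[2]
  }
  structure(list(a = a, b = b, c = c, d = d), class = "cov_params")
}

#' @export
print.cov_params <- function(x, ...) {
  cat(sprintf(
    "AB covariance: exp(%.3g - r^2/%.5g^2) + exp(%.3g - r^2/%.5g^2)  [k(0) = %.4g]\n",
    x$a, x$b, x$c, x$d, exp(x$a) + exp(x$c)))
  invisible(x)
}

#' Evaluate the AB covariance function
#'
#' @param x1,x2 Genomic positions in bp (vectors are recycled).
#' @param params A [cov_params()] object.
#' @return Covariance value(s); depends only on `|x1 - x2|`.
#' @examples
#' ab_covariance(100, 600, cov_params(0, 1000, 0, 100))
#' @export
ab_covariance <- function(x1, x2, params) {
  stopifnot(inherits(params, "cov_params"))
  if (!all(is.finite(x1), is.finite(x2))) abort("positions must be finite")
  r2 <- (x1 - x2)^2
  exp(params$a - r2 / params$b^2) + exp(params$c - r2 / params$d^2)
}

# Dense covariance matrix over a position vector, with diagonal jitter
# proportional to the prior variance for factorization stability.
cov_matrix <- function(pos, params, jitter = 1e-6) {
  D2 <- outer(pos, pos, function(u, v) (u - v)^2)
  K <- exp(params$a - D2 / params$b^2) + exp(params$c - D2 / params$d^2)
  diag(K) <- diag(K) + jitter * (exp(params$a) + exp(params$c))
  K
}

#' Default covariance-parameter search grid
#'
#' Log-amplitudes span strong to negligible components; the long length
#' scale spans sub-amplicon to well beyond MDA amplicon scale (~5-10 kb) and
#' the short scale spans read-length effects. Only combinations with
#' `d <= b` are kept.
#'
#' @param a,c Candidate log-amplitudes.
#' @param b,d Candidate length scales (bp).
#' @return A tibble with columns `a`, `b`, `c`, `d`, one row per grid point.
#' @export
ab_param_grid <- function(a = base::c(-6, -4, -2, -1, 0, 1),
                          b = base::c(500, 1000, 2000, 5000, 10000, 20000, 50000),
                          c = base::c(-6, -4, -2, -1, 0, 1),
                          d = base::c(10, 50, 150, 300, 1000)) {
  g <- tidyr::expand_grid(a = a, b = b, c = c, d = d)
  dplyr::filter(g, .data$d <= .data$b)
}
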