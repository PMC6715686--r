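#' Laplace approximation for one block of hSNPs
#'
#' Approximates the posterior of the latent logit-scale allele balance at a
#' set of phased hSNPs under the binomial-observation GP model. The posterior
#' mode is found by Newton-Raphson (initialized at B = 0) and iteration stops
#' when the relative change in the unnormalized log posterior falls below
#' `tol` or after `max_iter` iterations. The returned `log_marginal` is the
#' Laplace estimate of the block's marginal likelihood (model evidence),
#' including the binomial normalizing constants.
#'
#' @param block A data frame with columns `pos`, `allele1_reads`, `depth`
#'   (one row per hSNP; at most a few hundred rows — blocks of 100 are used
#'   during fitting).
#' @param params A [cov_params()] object.
#' @param jitter Relative diagonal jitter added to the covariance matrix.
#' @param max_iter,tol Newton-Raphson controls; `tol` defaults to
#'   \eqn{\sqrt{2.2\times 10^{-16}}}.
#' @return A list of class `laplace_fit` with elements `positions`, `b_hat`
#'   (posterior modes), `w_diag` (negative-Hessian diagonal of the
#'   likelihood), `log_marginal`, `iterations`, `converged`.
#' @export
laplace_block <- function(block, params, jitter = 1e-6, max_iter = 50,
                          tol = sqrt(.Machine$double.eps)) {
  stopifnot(all(c("pos", "allele1_reads", "depth") %in% names(block)))
  n <- nrow(block)
  if (n < 1) abort("laplace_block() requires at least one hSNP")
  if (any(block$depth < 1) || any(block$allele1_reads < 0) ||
      any(block$allele1_reads > block$depth))
    abort("invalid read counts: need 0 <= allele1_reads <= depth, depth >= 1")
  K <- cov_matrix(block$pos, params, jitter)
  fit <- .laplace_fit_cpp(K, as.numeric(block$allele1_reads),
                          as.numeric(block$depth), max_iter, tol)
  structure(list(positions = block$pos, b_hat = as.numeric(fit$b_hat),
                 w_diag = as.numeric(fit$w_diag),
                 log_marginal = fit$log_marginal,
                 iterations = fit$iterations, converged = fit$converged),
            class = "laplace_fit")
}

# Split row indices 1..n into consecutive blocks of `size`; a trailing
# remainder forms its own (smaller) block.
block_indices <- function(n, size = 100) {
  if (n < 1) return(list())
  split(seq_len(n), ceiling(seq_len(n) / size))
}

#' Fit the AB covariance function to one chromosome's hSNPs
#'
#' Maximizes the (approximate) marginal likelihood over a parameter grid.
#' The chromosome is split into consecutive blocks of `block_size` hSNPs
#' treated as independent; each block's evidence is computed by the Laplace
#' approximation and summed, and the grid point with the largest total wins.
#' Fit one chromosome at a time: AB correlation structure can differ between
#' chromosomes and samples.
#'
#' @param hsnps A data frame of phase-standardized hSNPs with columns `pos`,
#'   `allele1_reads`, `depth` (a single chromosome; see
#'   [read_phased_hsnps()]).
#' @param grid A data frame of candidate `(a, b, c, d)` values, default
#'   [ab_param_grid()].
#' @param block_size hSNPs per independent block (default 100).
#' @param jitter,max_iter,tol Passed to the Laplace core.
#' @return An object of class `ab_fit`: a list with `params` (the winning
#'   [cov_params()]), `grid` (tibble of all grid points with their summed
#'   `log_lik`), `n_hsnps`, `n_blocks`, `block_size`.
#' @seealso [tidy.ab_fit()], [glance.ab_fit()], [autoplot.ab_fit()]
#' @export
fit_ab_params <- function(hsnps, grid = ab_param_grid(), block_size = 100,
                          jitter = 1e-6, max_iter = 50,
                          tol = sqrt(.Machine$double.eps)) {
  if (nrow(hsnps) < 1) abort("need at least one hSNP to fit")
  if ("chrom" %in% names(hsnps) && dplyr::n_distinct(hsnps$chrom) > 1)
    abort("fit_ab_params() fits a single chromosome; split by chrom first")
  hsnps <- arrange(hsnps, .data$pos)
  grid <- arrange(as_tibble(grid), .data$b, .data$d, .data$a, .data$c)
  gmat <- as.matrix(grid[, c("a", "b", "c", "d")])
  blocks <- block_indices(nrow(hsnps), block_size)
  total <- numeric(nrow(grid))
  for (idx in blocks) {
    pos <- hsnps$pos[idx]
    D2 <- outer(pos, pos, function(u, v) (u - v)^2)
    total <- total + .grid_logz_cpp(D2, as.numeric(hsnps$allele1_reads[idx]),
                                    as.numeric(hsnps$depth[idx]), gmat,
                                    jitter, max_iter, tol)
  }
  if (all(!is.finite(total)))
    abort("all grid evaluations were non-finite; check input counts")
  grid$log_lik <- total
  best <- which.max(total)
  structure(list(
    params = cov_params(gmat[best, 1], gmat[best, 2], gmat[best, 3], gmat[best, 4]),
    grid = grid, n_hsnps = nrow(hsnps), n_blocks = length(blocks),
    block_size = block_size), class = "ab_fit")
}

#' @export
print.ab_fit <- function(x, ...) {
  cat(sprintf("AB model fit: %d hSNPs in %d blocks; best of %d grid points\n",
              x$n_hsnps, x$n_blocks, nrow(x$grid)))
  print(x$params)
  invisible(x)
}

#' Predict allele balance at arbitrary positions
#'
#' For each query position, hSNPs within `window` bp (capped at the nearest
#' `max_per_side` on each side) are fit by the Laplace approximation and the
#' GP posterior mean and variance of the latent logit-AB are computed. When
#' no hSNP falls in the window the GP prior is returned (`mu = 0`,
#' `sigma2 = k(x, x)`) and the site is flagged `ab_uninformed`.
#'
#' @param x Query positions (bp), one chromosome.
#' @param hsnps Phase-standardized hSNPs of the same chromosome (`pos`,
#'   `allele1_reads`, `depth`).
#' @param params A [cov_params()] object (typically `fit$params` from
#'   [fit_ab_params()]).
#' @param window Half-width in bp of the hSNP window around each query
#'   position (default 200 kb).
#' @param max_per_side Cap on hSNPs used per side of the query.
#' @param jitter,max_iter,tol Laplace controls.
#' @return A tibble with columns `pos`, `mu`, `sigma2` (logit scale), `ab`
#'   (`= logistic(mu)`), `n_hsnps_window`, `ab_uninformed`.
#' @export
predict_ab <- function(x, hsnps, params, window = 2e5, max_per_side = 100,
                       jitter = 1e-6, max_iter = 50,
                       tol = sqrt(.Machine$double.eps)) {
  stopifnot(inherits(params, "cov_params"))
  hsnps <- arrange(hsnps, .data$pos)
  prior_var <- exp(params$a) + exp(params$c)
  res <- purrr::map(x, function(xi) {
    lo <- findInterval(xi - window, hsnps$pos) + 1
    hi <- findInterval(xi + window, hsnps$pos)
    idx <- if (hi >= lo) lo:hi else integer(0)
    if (length(idx) > 0) { # cap at nearest max_per_side per side
      left <- idx[hsnps$pos[idx] <= xi]
      right <- idx[hsnps$pos[idx] > xi]
      idx <- c(utils::tail(left, max_per_side), head(right, max_per_side))
    }
    if (length(idx) == 0)
      return(list(mu = 0, sigma2 = prior_var, n = 0L, uninformed = TRUE))
    K <- cov_matrix(hsnps$pos[idx], params, jitter)
    kstar <- matrix(ab_covariance(hsnps$pos[idx], xi, params), ncol = 1)
    pred <- .laplace_predict_cpp(K, as.numeric(hsnps$allele1_reads[idx]),
                                 as.numeric(hsnps$depth[idx]), kstar,
                                 prior_var, max_iter, tol)
    list(mu = as.numeric(pred$mu), sigma2 = max(as.numeric(pred$sigma2), 0),
         n = length(idx), uninformed = FALSE)
  })
  tibble(pos = x,
         mu = purrr::map_dbl(res, "mu"),
         sigma2 = purrr::map_dbl(res, "sigma2"),
         ab = logistic(purrr::map_dbl(res, "mu")),
         n_hsnps_window = purrr::map_int(res, "n"),
         ab_uninformed = purrr::map_lgl(res, "uninformed"))
}
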