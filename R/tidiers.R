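#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the covariance-parameter grid search
#'
#' @param x An `ab_fit` from [fit_ab_params()].
#' @param ... Unused.
#' @return A tibble with one row per grid point (`a`, `b`, `c`, `d`,
#'   `log_lik`) sorted by decreasing log-likelihood.
#' @method tidy ab_fit
#' @export
tidy.ab_fit <- function(x, ...) {
  arrange(x$grid, dplyr::desc(.data$log_lik))
}

#' One-row summary of an AB model fit
#'
#' @param x An `ab_fit` from [fit_ab_params()].
#' @param ... Unused.
#' @return A one-row tibble with the selected parameters, their
#'   log-likelihood and fit sizes.
#' @method glance ab_fit
#' @export
glance.ab_fit <- function(x, ...) {
  tibble(a = x$params$a, b = x$params$b, c = x$params$c, d = x$params$d,
         log_lik = max(x$grid$log_lik), n_hsnps = x$n_hsnps,
         n_blocks = x$n_blocks, n_grid = nrow(x$grid))
}

#' Per-stratum summary of a burden table
#'
#' @param x A `burden_table` from [estimate_burden()].
#' @param ... Unused.
#' @return A tibble with one row per depth stratum: hSNP and candidate
#'   totals and the estimated true-mutation upper bound.
#' @method glance burden_table
#' @export
glance.burden_table <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$stratum, .data$depth) |>
    summarise(h_total = sum(.data$h), s_total = sum(.data$s),
              n_t = .data$n_t[1], .groups = "drop") |>
    arrange(.data$depth)
}
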