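# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_col labs theme_minimal scale_color_manual position_dodge
#' @export
ggplot2::autoplot

#' Plot the inferred allele-balance profile over a region
#'
#' Draws the posterior AB curve with a 95% credible envelope (logistic
#' transform of `mu +/- 1.96 sd`) and the phase-standardized hSNP
#' observations (`allele1_reads / depth`).
#'
#' @param hsnps Phased hSNPs of one chromosome.
#' @param params Fitted [cov_params()].
#' @param from,to Region bounds in bp (default: hSNP range).
#' @param n_grid Prediction grid size.
#' @param ... Passed to [predict_ab()].
#' @return A ggplot.
#' @export
plot_ab_profile <- function(hsnps, params, from = NULL, to = NULL,
                            n_grid = 200, ...) {
  if (is.null(from)) from <- min(hsnps$pos)
  if (is.null(to)) to <- max(hsnps$pos)
  grid <- seq(from, to, length.out = n_grid)
  pred <- predict_ab(grid, hsnps, params, ...)
  pred$lo <- logistic(pred$mu - 1.96 * sqrt(pred$sigma2))
  pred$hi <- logistic(pred$mu + 1.96 * sqrt(pred$sigma2))
  hs <- filter(hsnps, .data$pos >= from, .data$pos <= to)
  ggplot(pred, aes(x = .data$pos)) +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi), fill = "grey80") +
    geom_line(aes(y = .data$ab)) +
    geom_point(data = hs, aes(x = .data$pos,
                              y = .data$allele1_reads / .data$depth),
               color = "steelblue", size = 0.8) +
    labs(x = "position (bp)", y = "allele balance",
         title = "Posterior allele balance with 95% envelope") +
    theme_minimal()
}

#' Profile likelihood of the fitted covariance grid
#'
#' Shows, for each long-range length scale `b`, the best log-likelihood
#' over the remaining grid dimensions; the selected `b` is highlighted.
#'
#' @param object An `ab_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ab_fit
#' @export
autoplot.ab_fit <- function(object, ...) {
  prof <- object$grid |>
    group_by(.data$b) |>
    summarise(log_lik = max(.data$log_lik), .groups = "drop")
  ggplot(prof, aes(x = .data$b, y = .data$log_lik)) +
    geom_line() + geom_point() +
    geom_point(data = filter(prof, .data$b == object$params$b),
               color = "red", size = 3) +
    ggplot2::scale_x_log10() +
    labs(x = "long-range length scale b (bp)",
         y = "profile log-likelihood",
         title = "Covariance length-scale profile") +
    theme_minimal()
}

#' VAF spectrum of a burden table
#'
#' hSNP and candidate VAF distributions (summed over depth strata), each
#' normalized to unit mass; artifact enrichment shows up as excess candidate
#' mass at low VAF.
#'
#' @param object A `burden_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot burden_table
#' @export
autoplot.burden_table <- function(object, ...) {
  agg <- as_tibble(object) |>
    group_by(.data$bin) |>
    summarise(hSNP = sum(.data$h), candidate = sum(.data$s), .groups = "drop") |>
    mutate(vaf = (.data$bin - 0.5) * 0.05,
           hSNP = .data$hSNP / max(1, sum(.data$hSNP)),
           candidate = .data$candidate / max(1, sum(.data$candidate))) |>
    tidyr::pivot_longer(c("hSNP", "candidate"), names_to = "set",
                        values_to = "density")
  ggplot(agg, aes(x = .data$vaf, y = .data$density, fill = .data$set)) +
    geom_col(position = position_dodge(), width = 0.02) +
    labs(x = "VAF", y = "fraction of sites", fill = NULL,
         title = "hSNP vs candidate VAF spectrum") +
    theme_minimal()
}

#' Plot QC VAF densities and the doublet band
#'
#' @param object An `ab_qc` report from [qc_diagnostics()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ab_qc
#' @export
autoplot.ab_qc <- function(object, ...) {
  long <- object$bins |>
    mutate(vaf = (.data$bin_lo + .data$bin_hi) / 2) |>
    tidyr::pivot_longer(c("hsnp", "ssnv", "downsampled_hsnp"),
                        names_to = "set", values_to = "density")
  ggplot(long, aes(x = .data$vaf, y = .data$density, color = .data$set)) +
    ggplot2::annotate("rect", xmin = object$band[1], xmax = object$band[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.1, fill = "red") +
    geom_line() +
    labs(x = "VAF", y = "fraction of sites", color = NULL,
         title = sprintf("VAF spectra (doublet score %.3f)",
                         object$doublet_score)) +
    theme_minimal()
}
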