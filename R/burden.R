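# Artifact-burden estimation and FDR-targeted threshold tuning. The somatic
# candidate set is a mixture of true mutations (whose VAF distribution should
# mirror hSNPs, both being 50%-of-template variants subject to the same
# allelic imbalance) and artifacts (enriched at low VAF). A multinomial
# consistency simulation bounds the true-mutation count N_T; the remainder
# per VAF bin is the artifact burden N_A used to tune artifact-test cutoffs.

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Bin VAFs into 20 equal bins
#'
#' Bins are half-open `[0, 0.05), [0.05, 0.10), ...` with a closed final bin
#' `[0.95, 1]`.
#'
#' @param vafs Numeric vector in `[0, 1]`.
#' @return An integer vector of 20 counts.
#' @export
bin_vafs <- function(vafs) {
  if (length(vafs) == 0) return(integer(20))
  if (any(!is.finite(vafs)) || any(vafs < 0 | vafs > 1))
    abort("VAFs must lie in [0, 1]")
  tabulate(vaf_bin(vafs), nbins = 20)
}

# bin index (1..20) of each VAF
vaf_bin <- function(vafs) pmin(floor(vafs / 0.05) + 1L, 20L)

#' Upper bound on the number of true somatic mutations
#'
#' Distributes trial counts `N_T` of true mutations across VAF bins
#' according to the hSNP VAF distribution (multinomial draws) and asks how
#' often every simulated bin fits beneath the observed candidate counts. The
#' returned bound is the largest `N_T` whose consistency fraction `F` is at
#' least `f_min`; the lenient default accounts for a single overfull bin out
#' of 20 already making a trial inconsistent.
#'
#' @param h_counts,s_counts 20-vectors of binned hSNP and candidate counts
#'   (see [bin_vafs()]).
#' @param n_sims Multinomial draws per trial value (default 1000).
#' @param seed RNG seed (the search is reproducible given the seed).
#' @param f_min Consistency-fraction threshold (default 0.005).
#' @param grid_size Number of geometrically spaced trial values between 1
#'   and the candidate total; the bracketing interval is then bisected to
#'   integer resolution.
#' @return The estimated upper bound `N_T` (integer, possibly 0).
#' @export
estimate_nt <- function(h_counts, s_counts, n_sims = 1000, seed = 1,
                        f_min = 0.005, grid_size = 50) {
  stopifnot(length(h_counts) == 20, length(s_counts) == 20)
  if (sum(s_counts) == 0) return(0L)
  if (sum(h_counts) == 0) abort("estimate_nt: no hSNPs in stratum")
  prob <- h_counts / sum(h_counts)
  n_max <- sum(s_counts)
  consistent_frac <- function(nt) {
    draws <- rmultinom(n_sims, nt, prob)
    mean(colSums(draws <= s_counts) == 20L)
  }
  with_seed_if(seed, {
    grid <- unique(round(exp(seq(0, log(n_max), length.out = grid_size))))
    fs <- vapply(grid, consistent_frac, numeric(1))
    ok <- which(fs >= f_min)
    if (length(ok) == 0) return(0L)
    lo <- grid[max(ok)]
    hi <- if (max(ok) < length(grid)) grid[max(ok) + 1L] else n_max
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (consistent_frac(mid) >= f_min) lo <- mid else hi <- mid
    }
    as.integer(lo)
  })
}

#' Per-bin expected true-mutation and artifact counts
#'
#' Splits the true-mutation bound across VAF bins proportional to the hSNP
#' distribution: `N_T,i = N_T H_i / H`. The artifact burden per bin is
#' `N_A,i = max(N_T (1 - H_i / H), 0.1)`; the 0.1 floor avoids FDR
#' estimates of exactly zero.
#'
#' @param n_t True-mutation upper bound from [estimate_nt()].
#' @param h_counts 20-vector of binned hSNP counts.
#' @return A tibble with columns `bin`, `nt_i`, `na_i`.
#' @export
per_bin_burden <- function(n_t, h_counts) {
  stopifnot(n_t >= 0, length(h_counts) == 20, sum(h_counts) > 0)
  frac <- h_counts / sum(h_counts)
  tibble(bin = 1:20, nt_i = n_t * frac, na_i = pmax(n_t * (1 - frac), 0.1))
}

# Depth-stratum label: exact depth up to the hSNP 90th percentile, one
# pooled stratum above it.
depth_stratum <- function(depth, p90) ifelse(depth > p90, "pooled", as.character(depth))

#' Depth-stratified burden table
#'
#' Applies [estimate_nt()] and [per_bin_burden()] separately to hSNPs and
#' candidates of the same sequencing depth; all sites deeper than the 90th
#' percentile of hSNP depths form one pooled stratum. Candidates at a depth
#' with no hSNPs are assigned to the nearest hSNP depth stratum.
#'
#' @param hsnps Tibble with `depth` and `raw_vaf` columns (phased hSNPs).
#' @param candidates Tibble with `sc_depth` and `vaf` columns.
#' @param n_sims,seed,f_min Passed to [estimate_nt()].
#' @return A tibble of class `burden_table`: one row per (stratum, VAF bin)
#'   with columns `stratum`, `depth`, `bin`, `h`, `s`, `n_t`, `nt_i`,
#'   `na_i`; the hSNP depth 90th percentile is stored in attribute `p90`.
#' @export
estimate_burden <- function(hsnps, candidates, n_sims = 1000, seed = 1,
                            f_min = 0.005) {
  stopifnot(nrow(hsnps) > 0)
  p90 <- unname(quantile(hsnps$depth, 0.9))
  h_strat <- depth_stratum(hsnps$depth, p90)
  cand_strat <- assign_stratum(candidates$sc_depth, hsnps$depth, p90)
  strata <- sort(unique(h_strat))
  rows <- purrr::imap(setNames(strata, strata), function(st, nm) {
    h_counts <- bin_vafs(hsnps$raw_vaf[h_strat == st])
    s_counts <- bin_vafs(candidates$vaf[cand_strat == st])
    nt <- estimate_nt(h_counts, s_counts, n_sims = n_sims,
                      seed = seed + which(strata == st), f_min = f_min)
    pb <- per_bin_burden(nt, h_counts)
    tibble(stratum = st,
           depth = if (st == "pooled") NA_real_ else as.numeric(st),
           bin = pb$bin, h = h_counts, s = s_counts, n_t = nt,
           nt_i = pb$nt_i, na_i = pb$na_i)
  })
  out <- bind_rows(rows)
  attr(out, "p90") <- p90
  class(out) <- c("burden_table", class(out))
  out
}

# map arbitrary depths onto the hSNP-defined strata (nearest exact depth;
# pooled above p90)
assign_stratum <- function(depth, hsnp_depths, p90) {
  avail <- sort(unique(hsnp_depths[hsnp_depths <= p90]))
  vapply(depth, function(d) {
    if (d > p90) return("pooled")
    if (length(avail) == 0) return("pooled")
    as.character(avail[which.min(abs(avail - d))])
  }, character(1))
}

# burden lookup for one candidate: (nt_i, na_i) of its VAF bin/depth stratum
burden_lookup <- function(burden, vaf, depth) {
  p90 <- attr(burden, "p90")
  hd <- burden$depth[!is.na(burden$depth)]
  st <- assign_stratum(depth, if (length(hd)) hd else p90 + 1, p90)
  b <- vaf_bin(vaf)
  row <- burden[burden$stratum == st & burden$bin == b, ]
  if (nrow(row) == 0) { # stratum absent entirely: fall back to pooled
    row <- burden[burden$stratum == "pooled" & burden$bin == b, ]
  }
  if (nrow(row) == 0) return(list(nt_i = 0, na_i = 0.1))
  list(nt_i = row$nt_i[1], na_i = row$na_i[1])
}

#' Tune an artifact-test p-value cutoff to a target FDR
#'
#' The artifact tests admit only finitely many achievable cutoffs: the tail
#' p-values of the `D + 1` possible read counts under the artifact null.
#' Outcomes are ordered by increasing null probability (highest-density
#' rejection regions, with equal-probability outcomes entering as a block);
#' for each achievable cutoff `alpha` the power `1 - beta` to reject the
#' artifact null is computed under the true-mutation alternative (the ABC
#' null at `mu*`), and the expected FDR follows from
#' \deqn{FDR = \alpha N_A / (\alpha N_A + (1-\beta) N_T).}
#' The largest `alpha` with FDR at most `theta` is returned; 0 if none
#' qualifies (the site is unpowered and can never reject the artifact
#' explanation).
#'
#' @param d Candidate depth.
#' @param mu,sigma2 AB posterior at the site.
#' @param vaf Candidate VAF (used to orient the alternative via
#'   [mu_star()]).
#' @param nt_i,na_i Expected true-mutation and artifact counts for the
#'   candidate's VAF bin and depth stratum (see [estimate_burden()]).
#' @param theta Target FDR (default 0.1).
#' @param f Artifact divisor, 2 or 4.
#' @param n_nodes Gauss-Hermite nodes.
#' @param tie_tol Probabilities closer than this are treated as tied.
#' @return The tuned cutoff `alpha` in `[0, 1]`.
#' @export
tune_alpha <- function(d, mu, sigma2, vaf, nt_i, na_i, theta = 0.1,
                       f = 2, n_nodes = 128, tie_tol = 1e-12) {
  g <- outcome_pmf(d, mu, sigma2, "artifact", f = f, n_nodes = n_nodes)
  h <- outcome_pmf(d, mu_star(vaf, mu), sigma2, "abc", n_nodes = n_nodes)
  ord <- order(g, seq_along(g))
  gs <- g[ord]; hs <- h[ord]
  cum_a <- cumsum(gs); cum_p <- cumsum(hs)
  # achievable cutoffs end at tie-group boundaries
  grp_end <- c(diff(gs) > tie_tol, TRUE)
  alpha <- cum_a[grp_end]; power <- cum_p[grp_end]
  fdr <- alpha * na_i / (alpha * na_i + power * nt_i)
  fdr[alpha * na_i + power * nt_i == 0] <- 0
  ok <- which(fdr <= theta)
  if (length(ok) == 0) 0 else min(max(alpha[ok]), 1)
}
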