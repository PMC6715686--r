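# Single-sample genotyping, the CIGAR excess filters, multi-sample joint
# calling, and QC diagnostics (doublet detection).

#' Genotype candidate somatic SNVs in one single cell
#'
#' For each candidate: predicts the local AB posterior from phased hSNPs,
#' runs the allele-balance consistency (ABC) test and both artifact tests,
#' tunes per-candidate artifact cutoffs to the target FDR from the burden
#' table, and applies the optional CIGAR excess filters.
#'
#' A candidate passes when (i) its ABC p-value is at least `abc_cutoff`
#' (the VAF is explainable by the local AB), (ii) each artifact null is
#' *rejected* at its tuned cutoff (`p <= alpha`; an artifact explanation
#' that cannot be rejected kills the call, including the `alpha = 0`
#' unpowered case), and (iii) no CIGAR excess flag is raised.
#'
#' @param candidates Candidate tibble from [select_candidates()] (one
#'   chromosome).
#' @param hsnps Phased hSNPs of the same chromosome from
#'   [read_phased_hsnps()].
#' @param params Fitted [cov_params()] for the chromosome.
#' @param burden Optional precomputed [estimate_burden()] table; computed
#'   from `hsnps` and `candidates` when `NULL`.
#' @param target_fdr Target FDR for the artifact tests (default 0.1).
#' @param abc_cutoff Fixed ABC p-value cutoff (default 0.05).
#' @param window,max_per_side Passed to [predict_ab()].
#' @param n_nodes Gauss-Hermite node count.
#' @param cand_cigar,hsnp_cigar Optional CIGAR-fraction tibbles (see
#'   [read_cigar_profiles()]); the filter is skipped with a warning when
#'   absent.
#' @param seed Seed for burden estimation and CIGAR hSNP subsampling.
#' @return A tibble of class `ab_calls`, one row per candidate, with AB
#'   posterior (`mu`, `sigma2`, `ab`), p-values (`p_abc`, `p_preamp`,
#'   `p_amp`), tuned cutoffs (`alpha_preamp`, `alpha_amp`), flag columns,
#'   a semicolon-joined `filters` string and `pass`. The burden table is
#'   attached as attribute `"burden"`.
#' @export
genotype_single <- function(candidates, hsnps, params, burden = NULL,
                            target_fdr = 0.1, abc_cutoff = 0.05,
                            window = 2e5, max_per_side = 100, n_nodes = 128,
                            cand_cigar = NULL, hsnp_cigar = NULL, seed = 1) {
  stopifnot(inherits(params, "cov_params"))
  if (is.null(burden))
    burden <- estimate_burden(hsnps, candidates, seed = seed)
  ab <- predict_ab(candidates$pos, hsnps, params, window = window,
                   max_per_side = max_per_side)
  out <- candidates
  out$mu <- ab$mu; out$sigma2 <- ab$sigma2; out$ab <- ab$ab
  out$ab_uninformed <- ab$ab_uninformed
  out$low_depth <- out$sc_depth < 1
  res <- purrr::pmap(list(out$sc_alt, out$sc_depth, out$mu, out$sigma2,
                          out$vaf, out$low_depth),
    function(y, d, mu, s2, vaf, lowd) {
      if (lowd)
        return(list(p_abc = NA_real_, p_preamp = NA_real_, p_amp = NA_real_,
                    alpha_preamp = 0, alpha_amp = 0))
      bl <- burden_lookup(burden, vaf, d)
      list(p_abc = abc_test(y, d, mu, s2, n_nodes = n_nodes)$p_value,
           p_preamp = artifact_test(y, d, mu, s2, f = 2,
                                    n_nodes = n_nodes)$p_value,
           p_amp = artifact_test(y, d, mu, s2, f = 4,
                                 n_nodes = n_nodes)$p_value,
           alpha_preamp = tune_alpha(d, mu, s2, vaf, bl$nt_i, bl$na_i,
                                     theta = target_fdr, f = 2,
                                     n_nodes = n_nodes),
           alpha_amp = tune_alpha(d, mu, s2, vaf, bl$nt_i, bl$na_i,
                                  theta = target_fdr, f = 4,
                                  n_nodes = n_nodes))
    })
  for (nm in c("p_abc", "p_preamp", "p_amp", "alpha_preamp", "alpha_amp"))
    out[[nm]] <- purrr::map_dbl(res, nm)
  out$abc_fail <- !out$low_depth & out$p_abc < abc_cutoff
  out$preamp_fail <- !out$low_depth &
    !(out$p_preamp <= out$alpha_preamp + 1e-12)
  out$amp_fail <- !out$low_depth & !(out$p_amp <= out$alpha_amp + 1e-12)
  if (!is.null(cand_cigar) && !is.null(hsnp_cigar)) {
    cg <- cigar_filter(candidates, cand_cigar, hsnp_cigar, seed = seed)
    out$indel_excess <- cg$indel_excess
    out$clip_excess <- cg$clip_excess
  } else {
    if (xor(is.null(cand_cigar), is.null(hsnp_cigar)) ||
        (is.null(cand_cigar) && is.null(hsnp_cigar)))
      warn("CIGAR profiles not provided; indel/clip excess filters skipped")
    out$indel_excess <- FALSE
    out$clip_excess <- FALSE
  }
  flag_cols <- c("abc_fail", "preamp_fail", "amp_fail", "indel_excess",
                 "clip_excess", "low_depth")
  flag_mat <- as.matrix(out[, flag_cols])
  out$filters <- apply(flag_mat, 1, function(fl)
    paste(flag_cols[fl], collapse = ";"))
  out$pass <- rowSums(flag_mat) == 0
  attr(out, "burden") <- burden
  attr(out, "params") <- params
  class(out) <- c("ab_calls", class(out))
  out
}

#' Excess indel / read-clipping filter
#'
#' Flags candidates whose single-cell fraction of indel- or clip-carrying
#' reads is excessive relative to hSNPs with comparable bulk behavior: per
#' operation type, a candidate is flagged when its single-cell fraction
#' exceeds the 90th percentile of single-cell fractions among (up to
#' `n_sample` randomly drawn) hSNPs whose bulk fraction does not exceed the
#' candidate's (falling back to all sampled hSNPs when none qualify).
#'
#' @param candidates Candidate tibble (provides site order of the result).
#' @param cand_cigar Tibble with `chrom`, `pos`, `cell_indel`, `cell_clip`,
#'   `bulk_indel`, `bulk_clip` for candidates.
#' @param hsnp_cigar Same columns for hSNP sites.
#' @param n_sample hSNP profiles to subsample (default 4000; all if fewer).
#' @param seed Subsampling seed.
#' @param q Percentile defining excess (default 0.9).
#' @return A tibble with logical columns `indel_excess`, `clip_excess`
#'   aligned to `candidates` (missing profiles give `FALSE`).
#' @export
cigar_filter <- function(candidates, cand_cigar, hsnp_cigar, n_sample = 4000,
                         seed = 1, q = 0.9) {
  if (nrow(hsnp_cigar) < 1) abort("cigar_filter: need at least one hSNP profile")
  hs <- with_seed_if(seed, {
    if (nrow(hsnp_cigar) > n_sample)
      hsnp_cigar[sample.int(nrow(hsnp_cigar), n_sample), ]
    else hsnp_cigar
  })
  prof <- left_join(select(candidates, "chrom", "pos"), cand_cigar,
                    by = c("chrom", "pos"))
  flag_op <- function(cell_frac, bulk_frac, op) {
    h_cell <- hs[[paste0("cell_", op)]]
    h_bulk <- hs[[paste0("bulk_", op)]]
    purrr::map2_lgl(cell_frac, bulk_frac, function(cf, bf) {
      if (is.na(cf) || is.na(bf)) return(FALSE)
      ref <- h_cell[h_bulk <= bf]
      if (length(ref) == 0) ref <- h_cell
      cf > quantile(ref, q, names = FALSE)
    })
  }
  tibble(indel_excess = flag_op(prof$cell_indel, prof$bulk_indel, "indel"),
         clip_excess = flag_op(prof$cell_clip, prof$bulk_clip, "clip"))
}

# p_abc and GP sd for one sample at given sites; returns tibble rows aligned
# to `sites` (chrom/pos/alt_reads/depth), NA rows where depth < 1.
# exclude_self: drop a training hSNP co-located with the query (leave-one-out,
# used when the queried sites are themselves hSNPs so the AB posterior is not
# informed by the very reads being tested).
sample_abc <- function(sites, hsnps, params, window, max_per_side, n_nodes,
                       exclude_self = FALSE) {
  ab <- if (!exclude_self) {
    predict_ab(sites$pos, hsnps, params, window = window,
               max_per_side = max_per_side)
  } else {
    bind_rows(purrr::map(sites$pos, function(p)
      predict_ab(p, filter(hsnps, .data$pos != p), params, window = window,
                 max_per_side = max_per_side)))
  }
  p <- purrr::pmap_dbl(list(sites$alt_reads, sites$depth, ab$mu, ab$sigma2),
    function(y, d, mu, s2) {
      if (is.na(y) || is.na(d) || d < 1) return(NA_real_)
      abc_test(y, d, mu, s2, n_nodes = n_nodes)$p_value
    })
  tibble(p_abc = p, gp_sd = sqrt(ab$sigma2))
}

#' Joint calling across multiple single cells
#'
#' True mutations should be allele-balance consistent in every cell that
#' shows them. For each site, the joint statistic `J` is the product over
#' supporting samples (any mutation-supporting read) of the sample's ABC
#' p-value, each multiplied by a 1/10 penalty when the GP posterior sd at
#' the locus exceeds 1 (AB poorly determined). Thresholds come from `J`
#' computed at randomly drawn hSNPs, grouped by supporting-sample count: a
#' site passes when its `J` reaches the value exceeded by 90% of hSNPs in
#' its group (hSNPs behave like true variants, so 90% of them pass).
#' Artifact and CIGAR filters are not applied in joint mode.
#'
#' @param site_counts Tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `sample`, `alt_reads`, `depth`: per-sample read counts at candidate
#'   sites (absent rows are treated as no support).
#' @param hsnps Tibble of per-sample phased hSNPs: the
#'   [read_phased_hsnps()] columns plus `sample`.
#' @param params_by_sample Named list of [cov_params()], one per sample.
#' @param n_hsnp_sample hSNP sites drawn for threshold calibration
#'   (default 4000).
#' @param seed Subsampling seed.
#' @param pass_quantile Fraction of hSNP `J` values a passing site may
#'   undercut (default 0.1: the threshold retains 90% of hSNPs).
#' @param sd_penalty_threshold,penalty GP-sd penalty rule.
#' @param window,max_per_side,n_nodes Prediction/test controls.
#' @return A tibble of class `ab_joint_calls`, one row per site, with
#'   `n_support`, `j_stat`, `threshold`, `pass`; per-sample detail in
#'   attribute `"per_sample"` and group thresholds in `"thresholds"`.
#' @export
joint_call <- function(site_counts, hsnps, params_by_sample,
                       n_hsnp_sample = 4000, seed = 1, pass_quantile = 0.1,
                       sd_penalty_threshold = 1, penalty = 0.1,
                       window = 2e5, max_per_side = 100, n_nodes = 128) {
  samples <- unique(site_counts$sample)
  if (length(samples) < 2) abort("joint_call requires at least two samples")
  if (!all(samples %in% names(params_by_sample)))
    abort("params_by_sample must contain every sample in site_counts")
  per_sample <- site_counts |>
    filter(.data$alt_reads >= 1, .data$depth >= 1) |>
    dplyr::group_split(.data$sample) |>
    purrr::map(function(sc) {
      sm <- sc$sample[1]
      hs <- filter(hsnps, .data$sample == sm)
      dplyr::bind_cols(sc, sample_abc(sc, hs, params_by_sample[[sm]],
                                      window, max_per_side, n_nodes))
    }) |>
    bind_rows()
  j_of <- function(p, sd) prod(p * ifelse(sd > sd_penalty_threshold, penalty, 1))
  site_j <- per_sample |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(n_support = dplyr::n(),
              j_stat = j_of(.data$p_abc, .data$gp_sd), .groups = "drop")
  # hSNP-derived thresholds per support-count class
  hsnp_j <- with_seed_if(seed, {
    hsites <- distinct(hsnps, .data$chrom, .data$pos)
    if (nrow(hsites) > n_hsnp_sample)
      hsites <- hsites[sample.int(nrow(hsites), n_hsnp_sample), ]
    obs <- hsnps |>
      dplyr::semi_join(hsites, by = c("chrom", "pos")) |>
      filter(.data$alt_reads >= 1, .data$depth >= 1)
    obs |>
      dplyr::group_split(.data$sample) |>
      purrr::map(function(hh) {
        sm <- hh$sample[1]
        hs <- filter(hsnps, .data$sample == sm)
        dplyr::bind_cols(hh, sample_abc(hh, hs, params_by_sample[[sm]],
                                        window, max_per_side, n_nodes,
                                        exclude_self = TRUE))
      }) |>
      bind_rows() |>
      group_by(.data$chrom, .data$pos) |>
      summarise(n_support = dplyr::n(),
                j_stat = j_of(.data$p_abc, .data$gp_sd), .groups = "drop")
  })
  thresholds <- hsnp_j |>
    group_by(.data$n_support) |>
    summarise(threshold = quantile(.data$j_stat, pass_quantile, names = FALSE),
              n_hsnps = dplyr::n(), .groups = "drop")
  lookup_threshold <- function(k) {
    avail <- thresholds$n_support[thresholds$n_support <= k]
    if (length(avail) == 0) {
      inform(sprintf("no hSNP J reference for support class %d; using smallest class", k))
      avail <- min(thresholds$n_support)
    }
    thresholds$threshold[thresholds$n_support == max(avail)][1]
  }
  site_j$threshold <- purrr::map_dbl(site_j$n_support, lookup_threshold)
  site_j$pass <- site_j$j_stat >= site_j$threshold
  attr(site_j, "per_sample") <- per_sample
  attr(site_j, "thresholds") <- thresholds
  class(site_j) <- c("ab_joint_calls", class(site_j))
  site_j
}

#' QC diagnostics: VAF spectra and doublet score
#'
#' Compares the called-sSNV VAF distribution to the hSNP reference. hSNPs
#' show the VAF distribution expected of true (shared) heterozygous
#' mutations; binomially downsampling hSNP alt reads by half gives the
#' expectation for mutations present on 25% of template, as unshared sSNVs
#' in an accidental two-cell doublet would be. The doublet score is the
#' excess sSNV probability mass in the `band` VAF window (default
#' `[0.15, 0.35]`, around the characteristic 25% doublet peak) over the
#' hSNP mass in the same window; values near 0 are expected for a clean
#' single cell.
#'
#' @param hsnps Phased hSNP tibble (`alt_reads`, `depth`, `raw_vaf`).
#' @param ssnv_vafs VAFs of called (or high-confidence) sSNVs.
#' @param band VAF window scanned for doublet excess.
#' @param n_bins Histogram bins for the report.
#' @param seed Seed for the binomial downsampling.
#' @return A list of class `ab_qc`: `bins` (per-bin densities for hSNPs,
#'   sSNVs and the downsampled reference), `doublet_score`, `band`,
#'   `n_ssnv`, `n_hsnp`.
#' @export
qc_diagnostics <- function(hsnps, ssnv_vafs, band = c(0.15, 0.35),
                           n_bins = 40, seed = 1) {
  if (length(ssnv_vafs) < 100)
    warn("fewer than 100 sSNVs; the VAF histogram and doublet score are noisy")
  down_vaf <- with_seed_if(seed, {
    alt2 <- rbinom(nrow(hsnps), hsnps$alt_reads, 0.5)
    alt2 / hsnps$depth
  })
  breaks <- seq(0, 1, length.out = n_bins + 1)
  dens <- function(v) {
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    h$counts / max(1, length(v))
  }
  bins <- tibble(bin_lo = breaks[-(n_bins + 1)], bin_hi = breaks[-1],
                 hsnp = dens(hsnps$raw_vaf), ssnv = dens(ssnv_vafs),
                 downsampled_hsnp = dens(down_vaf))
  in_band <- function(v) mean(v >= band[1] & v <= band[2])
  score <- in_band(ssnv_vafs) - in_band(hsnps$raw_vaf)
  structure(list(bins = bins, doublet_score = score, band = band,
                 n_ssnv = length(ssnv_vafs), n_hsnp = nrow(hsnps)),
            class = "ab_qc")
}

#' @export
print.ab_qc <- function(x, ...) {
  cat(sprintf("QC report: %d sSNVs vs %d hSNPs; doublet score %.3f (band %.2f-%.2f)\n",
              x$n_ssnv, x$n_hsnp, x$doublet_score, x$band[1], x$band[2]))
  invisible(x)
}
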