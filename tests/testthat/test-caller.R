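# Single-sample genotyping, CIGAR filters, joint calling and QC.

# a severely imbalanced neighborhood (AB ~ 0.89) like the motivating
# high-VAF artifact example: deep hSNPs pin the AB, the candidate sits at
# VAF 0.44 -- half the over-amplified allele's balance
imbalanced_fixture <- function(ab = 0.89, n_hsnp = 12, depth = 40, seed = 81) {
  withr::with_seed(seed, {
    pos <- sort(sample(48000:53000, n_hsnp))
    y <- rbinom(n_hsnp, depth, ab)
    hs <- tibble::tibble(chrom = "chr1", pos = pos, alt_reads = y,
                         depth = depth, raw_vaf = y / depth,
                         hap_flip = FALSE, allele1_reads = y)
    hs
  })
}

test_that("a half-balance candidate in an imbalanced region is an artifact call", {
  hs <- imbalanced_fixture()
  cand <- tibble::tibble(chrom = "chr1", pos = 50500L, ref = "A", alt = "T",
                         sc_alt = 22L, sc_depth = 50L, bulk_alt = 0L,
                         bulk_depth = 30L, vaf = 0.44)
  suppressWarnings(
    calls <- genotype_single(cand, hs, default_truth(), target_fdr = 0.1))
  # AB posterior near the hSNP consensus
  expect_gt(calls$ab, 0.8)
  # VAF 0.44 vs AB ~0.89/0.11: strongly inconsistent
  expect_lt(calls$p_abc, 0.001)
  expect_true(calls$abc_fail)
  # but thoroughly consistent with a pre-amplification artifact (~ab/2)
  expect_gt(calls$p_preamp, 0.2)
  expect_true(calls$preamp_fail) # artifact null not rejected -> fails
  expect_false(calls$pass)
})

test_that("AB-matched candidates pass while simulated artifacts are rejected", {
  sim <- sim_dataset(sim_config(n_hsnps = 1200, n_true_ssnvs = 80,
                                n_preamp_artifacts = 80,
                                n_amp_artifacts = 80, depth_mean = 60,
                                seed = 82))
  suppressWarnings(
    calls <- genotype_single(sim$candidates, sim$hsnps, default_truth(),
                             target_fdr = 0.1))
  m <- dplyr::left_join(tibble::as_tibble(calls), sim$truth,
                        by = c("chrom", "pos"))
  # well-supported true mutations in informative regions are recovered
  strong <- m[m$role == "true_ssnv" & m$vaf >= 0.4, ]
  expect_gt(mean(strong$pass), 0.3)
  # labeled artifacts are overwhelmingly rejected
  art <- m[m$role != "true_ssnv", ]
  expect_lt(mean(art$pass), 0.05)
  # zero depth is flagged and auto-fails
  cand0 <- sim$candidates[1, ]
  cand0$sc_depth <- 0L; cand0$sc_alt <- 0L; cand0$vaf <- 0
  suppressWarnings(
    c0 <- genotype_single(cand0, sim$hsnps, default_truth(),
                          burden = attr(calls, "burden")))
  expect_true(c0$low_depth)
  expect_false(c0$pass)
  expect_match(c0$filters, "low_depth")
})

test_that("passing candidates still pass under a looser FDR target", {
  sim <- sim_dataset(sim_config(n_hsnps = 600, n_true_ssnvs = 40,
                                n_preamp_artifacts = 40, n_amp_artifacts = 0,
                                seed = 83))
  suppressWarnings(
    strict <- genotype_single(sim$candidates, sim$hsnps, default_truth(),
                              target_fdr = 0.05))
  suppressWarnings(
    loose <- genotype_single(sim$candidates, sim$hsnps, default_truth(),
                             target_fdr = 0.2))
  expect_gte(sum(loose$pass), sum(strict$pass))
  expect_true(all(loose$pass[strict$pass]))
  # tuned cutoffs are monotone in the target
  expect_true(all(loose$alpha_preamp >= strict$alpha_preamp - 1e-12))
})

test_that("CIGAR excess filter compares against bulk-conditioned hSNP percentiles", {
  withr::with_seed(84, {
    hsnp_prof <- tibble::tibble(chrom = "chr1", pos = 1:500 * 100L,
                                cell_indel = runif(500, 0, 0.1),
                                cell_clip = runif(500, 0, 0.1),
                                bulk_indel = runif(500, 0, 0.05),
                                bulk_clip = runif(500, 0, 0.05))
  })
  cand <- tibble::tibble(chrom = "chr1", pos = c(70L, 170L, 270L, 370L))
  cand_prof <- tibble::tibble(
    chrom = "chr1", pos = c(70L, 170L, 270L, 370L),
    cell_indel = c(0, 0.5, 0.05, 0.5),
    cell_clip = c(0, 0, 0.5, 0.05),
    bulk_indel = c(0, 0, 0, 0),
    bulk_clip = c(0, 0, 0.02, 0.02))
  fl <- cigar_filter(cand, cand_prof, hsnp_prof, seed = 1)
  # zero fraction can never exceed a nonnegative percentile
  expect_false(fl$indel_excess[1])
  # 0.5 far exceeds the ~0.09 percentile of uniform [0, 0.1] fractions
  expect_true(fl$indel_excess[2])
  expect_true(fl$clip_excess[3])
  # 0.05 sits at the median: not excessive
  expect_false(fl$indel_excess[3])
  expect_false(fl$clip_excess[4])
  # all-zero hSNP fractions flag any positive candidate fraction
  zero_prof <- dplyr::mutate(hsnp_prof, cell_indel = 0, cell_clip = 0,
                             bulk_indel = 0, bulk_clip = 0)
  fl0 <- cigar_filter(cand[2, ], cand_prof[2, ], zero_prof, seed = 1)
  expect_true(fl0$indel_excess)
  expect_false(fl0$clip_excess) # candidate clip fraction is 0
})

test_that("joint statistic is the penalized product of ABC p-values", {
  # one supporting sample: J is that sample's (possibly penalized) p
  # two samples at p = 0.4, one with sd > 1: J = 0.4 * 0.4/10
  p <- c(0.4, 0.4); sd <- c(0.5, 1.5)
  j <- prod(p * ifelse(sd > 1, 0.1, 1))
  expect_equal(j, 0.016)
})

test_that("joint calling recovers shared mutations across samples", {
  jd <- sim_joint_data(n_samples = 3, n_hsnps = 350, n_shared = 20,
                       n_private = 20, seed = 85)
  jc <- suppressMessages(
    joint_call(jd$site_counts, jd$hsnps, jd$params_by_sample,
               n_hsnp_sample = 250, seed = 1))
  m <- dplyr::left_join(tibble::as_tibble(jc), jd$truth, by = "pos")
  shared <- m[m$role == "shared", ]
  # shared true mutations are supported by every sample and mostly pass
  expect_true(all(shared$n_support == 3))
  expect_gt(mean(shared$pass), 0.6)
  # thresholds derive from the requested hSNP quantile
  th <- attr(jc, "thresholds")
  expect_true(all(th$threshold >= 0 & th$threshold <= 1))
  # J of a single-sample site is its own p-value: bounded by 1
  expect_true(all(m$j_stat <= 1 + 1e-12))
  expect_error(joint_call(jd$site_counts[jd$site_counts$sample == "cell1", ],
                          jd$hsnps, jd$params_by_sample), "two samples")
})

test_that("doublet score separates doublet from singlet simulations", {
  base <- list(n_hsnps = 1500, n_true_ssnvs = 300, n_preamp_artifacts = 0,
               n_amp_artifacts = 0)
  simd <- sim_dataset(do.call(sim_config, c(base, doublet = TRUE,
                                            shared_fraction = 0.5, seed = 86)))
  simn <- sim_dataset(do.call(sim_config, c(base, doublet = FALSE, seed = 86)))
  qd <- qc_diagnostics(simd$hsnps, simd$candidates$vaf)
  qn <- qc_diagnostics(simn$hsnps, simn$candidates$vaf)
  expect_gt(qd$doublet_score, 0.1)
  expect_lt(abs(qn$doublet_score), 0.05)
  # report bins account for all sites
  expect_equal(sum(qn$bins$ssnv), 1, tolerance = 1e-9)
  expect_equal(sum(qn$bins$hsnp), 1, tolerance = 1e-9)
  expect_warning(qc_diagnostics(simn$hsnps, runif(10)), "fewer than 100")
})
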