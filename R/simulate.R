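# Synthetic single-cell dataset generator. Emulates the statistical structure
# the caller assumes: a latent logit-AB curve drawn from the spatial GP
# prior, binomial read sampling at phased hSNPs, and somatic candidates that
# are either true heterozygous mutations (allele fraction = carrier-allele
# AB), pre-amplification lesions (half the carrier fraction), first-round
# amplification misincorporations (a quarter), or -- in doublet mode --
# unshared mutations starting on 25% of template DNA.

#' Simulation configuration
#'
#' Defaults describe a typical MDA-amplified single cell: mean hSNP spacing
#' 1500 bp, 30x sequencing depth, and a covariance function with a dominant
#' long-range component at MDA amplicon scale (b = 10 kb) plus a weak
#' sub-read-length component.
#'
#' @param params True [cov_params()] generating the AB curve.
#' @param n_hsnps Number of phased hSNPs.
#' @param hsnp_spacing_mean Mean inter-hSNP gap (bp; gaps are exponential).
#' @param depth_mean Mean single-cell depth (Poisson, truncated at >= 1).
#' @param n_true_ssnvs,n_preamp_artifacts,n_amp_artifacts Candidate site
#'   counts by class.
#' @param doublet Simulate an accidental two-cell doublet?
#' @param shared_fraction In doublet mode, fraction of true sSNVs shared by
#'   both cells (unshared ones start on 25% of template).
#' @param bulk_depth_mean Mean bulk depth at emitted sites.
#' @param seed RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(params = cov_params(a = -1, b = 10000, c = -2, d = 150),
                       n_hsnps = 1000, hsnp_spacing_mean = 1500,
                       depth_mean = 30, n_true_ssnvs = 50,
                       n_preamp_artifacts = 100, n_amp_artifacts = 100,
                       doublet = FALSE, shared_fraction = 0.5,
                       bulk_depth_mean = 30, seed = 1) {
  stopifnot(inherits(params, "cov_params"), n_hsnps >= 1,
            hsnp_spacing_mean > 0, depth_mean > 0,
            n_true_ssnvs >= 0, n_preamp_artifacts >= 0, n_amp_artifacts >= 0,
            shared_fraction >= 0, shared_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Draw a latent AB curve from the GP prior
#'
#' Exact multivariate-normal draw with covariance `k` evaluated at
#' `positions` (plus diagonal jitter).
#'
#' @param positions Sorted genomic positions (bp).
#' @param params A [cov_params()] object.
#' @param seed Optional RNG seed.
#' @param jitter Relative diagonal jitter.
#' @return Numeric vector of latent logit-scale AB values.
#' @export
simulate_ab <- function(positions, params, seed = NULL, jitter = 1e-6) {
  if (is.unsorted(positions)) abort("positions must be sorted")
  K <- cov_matrix(positions, params, jitter)
  L <- tryCatch(chol(K), error = function(e)
    abort("covariance matrix is not positive definite"))
  with_seed_if(seed, as.numeric(crossprod(L, rnorm(length(positions)))))
}

# Poisson truncated at >= 1 via inverse cdf
rpois_pos <- function(n, lambda) {
  qpois(runif(n, dpois(0, lambda), 1), lambda)
}

#' Expected variant allele fraction by site class
#'
#' For a locus with allele balance `ab` (fraction of amplified DNA from the
#' carrier allele): a true heterozygous mutation is carried by all amplicons
#' of its allele (expected VAF `ab`); a single-stranded pre-amplification
#' lesion by half of them (`ab / 2`, i.e. `f = 2`); a first-round
#' amplification misincorporation by a quarter (`ab / 4`, `f = 4`, the
#' 1-of-8-strands case of an idealized 4-to-8 strand MDA start). With
#' balanced amplification (`ab = 0.5`) these give 50%, 25% and 12.5% of
#' total DNA respectively.
#'
#' @param ab Carrier-allele amplification balance in `[0, 1]`.
#' @param role One of `"mutation"`, `"preamp"`, `"amp"`.
#' @return Expected VAF.
#' @examples
#' expected_vaf(0.94, "preamp") # 0.47
#' expected_vaf(0.5, "amp")     # 0.125
#' @export
expected_vaf <- function(ab, role = c("mutation", "preamp", "amp")) {
  role <- match.arg(role)
  stopifnot(all(ab >= 0 & ab <= 1))
  ab / c(mutation = 1, preamp = 2, amp = 4)[[role]]
}

#' Simulate read counts at sites with known roles
#'
#' Each site draws a truncated-Poisson depth and binomial variant reads with
#' success probability determined by its role and the local AB: hSNPs and
#' true sSNVs use the carrier-allele fraction (the alt/mutant allele is
#' assigned to haplotype 1 or 2 uniformly), pre-amplification artifacts half
#' of it, amplification artifacts a quarter. In doublet mode, unshared true
#' sSNVs are present in only one of the two mixed cells and use half the
#' carrier fraction (25% of template when mixing is balanced).
#'
#' @param positions Site positions (bp).
#' @param B Latent logit-AB at each position (see [simulate_ab()]).
#' @param roles Character vector per site: `"hsnp"`, `"true_ssnv"`,
#'   `"preamp"` or `"amp"`.
#' @param depth_mean Mean sequencing depth.
#' @param doublet,shared_fraction Doublet mode controls (see
#'   [sim_config()]).
#' @param seed Optional RNG seed.
#' @return A tibble with columns `pos`, `role`, `B`, `ab`, `hap` (haplotype
#'   carrying the alt/mutant allele), `shared`, `true_frac` (expected VAF),
#'   `alt_reads`, `depth`, `vaf`.
#' @export
simulate_reads <- function(positions, B, roles, depth_mean = 30,
                           doublet = FALSE, shared_fraction = 0.5,
                           seed = NULL) {
  stopifnot(length(positions) == length(B), length(B) == length(roles),
            all(roles %in% c("hsnp", "true_ssnv", "preamp", "amp")))
  with_seed_if(seed, {
    n <- length(positions)
    ab <- logistic(B)
    hap <- sample(c(1L, 2L), n, replace = TRUE)
    carrier <- ifelse(hap == 1L, ab, 1 - ab)
    shared <- rep(TRUE, n)
    if (doublet) {
      is_true <- roles == "true_ssnv"
      shared[is_true] <- runif(sum(is_true)) < shared_fraction
    }
    divisor <- dplyr::case_when(
      roles %in% c("hsnp", "true_ssnv") & shared ~ 1,
      roles == "true_ssnv" & !shared ~ 2,
      roles == "preamp" ~ 2,
      roles == "amp" ~ 4)
    true_frac <- carrier / divisor
    depth <- rpois_pos(n, depth_mean)
    alt <- rbinom(n, depth, true_frac)
    tibble(pos = positions, role = roles, B = B, ab = ab, hap = hap,
           shared = shared, true_frac = true_frac,
           alt_reads = alt, depth = depth, vaf = alt / depth)
  })
}

#' Simulate a complete labeled dataset
#'
#' Lays out hSNPs and candidate sSNV sites along one chromosome, draws the
#' latent AB curve from the GP prior, simulates single-cell and bulk read
#' counts, and returns loader-compatible tables plus truth labels.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `ab_sim` with elements `hsnps` (phase-standardized,
#'   as returned by [read_phased_hsnps()]), `candidates` (as returned by
#'   [select_candidates()]), `truth` (per-site labels), `sites` (all raw
#'   per-site draws) and `config`.
#' @export
sim_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_if(config$seed, {
    n_cand <- config$n_true_ssnvs + config$n_preamp_artifacts +
      config$n_amp_artifacts
    n <- config$n_hsnps + n_cand
    # gap mean scaled so hSNP spacing keeps its configured mean
    gap_mean <- config$hsnp_spacing_mean * config$n_hsnps / n
    positions <- cumsum(round(rexp(n, 1 / gap_mean)) + 1)
    roles <- sample(c(rep("hsnp", config$n_hsnps),
                      rep("true_ssnv", config$n_true_ssnvs),
                      rep("preamp", config$n_preamp_artifacts),
                      rep("amp", config$n_amp_artifacts)))
    B <- simulate_ab(positions, config$params)
    sites <- simulate_reads(positions, B, roles, config$depth_mean,
                            doublet = config$doublet,
                            shared_fraction = config$shared_fraction)
    sites$chrom <- "chr1"
    bases <- c("A", "C", "G", "T")
    sites$ref <- sample(bases, n, replace = TRUE)
    sites$alt <- purrr::map_chr(sites$ref, ~ sample(setdiff(bases, .x), 1))
    # bulk: heterozygous at hSNPs, reference-only at somatic candidates
    sites$bulk_depth <- rpois_pos(n, config$bulk_depth_mean)
    sites$bulk_alt <- ifelse(sites$role == "hsnp",
                             rbinom(n, sites$bulk_depth, 0.5), 0L)
    hs <- filter(sites, .data$role == "hsnp", .data$depth >= 1)
    hsnps <- tibble(chrom = hs$chrom, pos = hs$pos, ref = hs$ref,
                    alt = hs$alt, alt_reads = hs$alt_reads,
                    depth = hs$depth, raw_vaf = hs$vaf,
                    hap_flip = hs$hap == 2L,
                    allele1_reads = ifelse(hs$hap == 2L,
                                           hs$depth - hs$alt_reads,
                                           hs$alt_reads))
    cand <- filter(sites, .data$role != "hsnp")
    candidates <- tibble(chrom = cand$chrom, pos = cand$pos, ref = cand$ref,
                         alt = cand$alt, sc_alt = cand$alt_reads,
                         sc_depth = cand$depth, bulk_alt = cand$bulk_alt,
                         bulk_depth = cand$bulk_depth,
                         vaf = cand$vaf)
    truth <- select(cand, "chrom", "pos", "role", "shared", "ab",
                    "true_frac")
    structure(list(hsnps = hsnps, candidates = candidates, truth = truth,
                   sites = sites, config = config), class = "ab_sim")
  })
}

#' Write a simulated dataset to disk in loader formats
#'
#' Emits a phased-genotype VCF for the hSNPs, a joint read-count TSV (bulk
#' and single-cell columns) covering all sites, and a truth-label TSV, in
#' exactly the formats [read_phased_hsnps()] and [select_candidates()]
#' consume.
#'
#' @param sim An [sim_dataset()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param bulk_sample,cell_sample Sample names used in the counts header.
#' @return Invisibly, a named list of the written paths.
#' @export
write_sim_dataset <- function(sim, dir, prefix = "sim", bulk_sample = "bulk",
                              cell_sample = "cell") {
  stopifnot(inherits(sim, "ab_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(vcf = file.path(dir, paste0(prefix, ".hsnps.vcf")),
                counts = file.path(dir, paste0(prefix, ".counts.tsv")),
                truth = file.path(dir, paste0(prefix, ".truth.tsv")))
  hs <- sim$hsnps
  gt <- ifelse(hs$hap_flip, "0|1", "1|0")
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "donor", sep = "\t"),
    paste(hs$chrom, hs$pos, ".", hs$ref, hs$alt, ".", "PASS", ".", "GT", gt,
          sep = "\t"))
  writeLines(vcf_lines, paths$vcf)
  st <- arrange(sim$sites, .data$pos)
  counts <- tibble(chrom = st$chrom, pos = st$pos, ref = st$ref,
                   alt = st$alt)
  counts[[paste0(bulk_sample, "_ref")]] <- st$bulk_depth - st$bulk_alt
  counts[[paste0(bulk_sample, "_alt")]] <- st$bulk_alt
  counts[[paste0(cell_sample, "_ref")]] <- st$depth - st$alt_reads
  counts[[paste0(cell_sample, "_alt")]] <- st$alt_reads
  readr::write_tsv(counts, paths$counts)
  readr::write_tsv(sim$truth, paths$truth)
  invisible(paths)
}
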