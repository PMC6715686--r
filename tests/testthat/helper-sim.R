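# Shared simulation helpers for the tests.

default_truth <- function() cov_params(a = -1, b = 10000, c = -2, d = 150)

# quick hSNP table drawn from the model truth
sim_hsnps <- function(n, params = default_truth(), spacing = 1500,
                      depth_mean = 30, seed = 1) {
  withr::with_seed(seed, {
    pos <- cumsum(round(rexp(n, 1 / spacing)) + 1)
    B <- simulate_ab(pos, params)
    d <- pmax(1L, rpois(n, depth_mean))
    hap <- sample(1:2, n, replace = TRUE)
    carrier <- ifelse(hap == 1, plogis(B), 1 - plogis(B))
    y <- rbinom(n, d, carrier)
    tibble::tibble(chrom = "chr1", pos = pos, alt_reads = y, depth = d,
                   raw_vaf = y / d, hap_flip = hap == 2,
                   allele1_reads = ifelse(hap == 2, d - y, y), B = B)
  })
}

# multi-sample dataset: shared germline hSNPs and true sSNVs across samples,
# private pre-amplification artifacts confined to the first sample
sim_joint_data <- function(n_samples = 3, n_hsnps = 400, n_shared = 25,
                           n_private = 25, depth_mean = 30,
                           params = default_truth(), seed = 1) {
  withr::with_seed(seed, {
    n <- n_hsnps + n_shared + n_private
    pos <- cumsum(round(rexp(n, 1 / 1500)) + 1)
    role <- sample(c(rep("hsnp", n_hsnps), rep("shared", n_shared),
                     rep("private", n_private)))
    hap <- sample(1:2, n, replace = TRUE)
    samples <- paste0("cell", seq_len(n_samples))
    hs <- list(); cnt <- list()
    for (sm in samples) {
      B <- simulate_ab(pos, params)
      carrier <- ifelse(hap == 1, plogis(B), 1 - plogis(B))
      d <- pmax(1L, rpois(n, depth_mean))
      frac <- ifelse(role == "private", carrier / 2, carrier)
      present <- role != "private" | sm == samples[1]
      y <- ifelse(present, rbinom(n, d, frac), 0L)
      ih <- role == "hsnp"
      hs[[sm]] <- tibble::tibble(
        chrom = "chr1", pos = pos[ih], alt_reads = y[ih], depth = d[ih],
        raw_vaf = y[ih] / d[ih], hap_flip = hap[ih] == 2,
        allele1_reads = ifelse(hap[ih] == 2, d[ih] - y[ih], y[ih]),
        sample = sm)
      ic <- role != "hsnp"
      cnt[[sm]] <- tibble::tibble(chrom = "chr1", pos = pos[ic], ref = "A",
                                  alt = "T", sample = sm,
                                  alt_reads = y[ic], depth = d[ic])
    }
    list(hsnps = dplyr::bind_rows(hs), site_counts = dplyr::bind_rows(cnt),
         truth = tibble::tibble(pos = pos[role != "hsnp"],
                                role = role[role != "hsnp"]),
         samples = samples,
         params_by_sample = setNames(rep(list(params), n_samples), samples))
  })
}
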