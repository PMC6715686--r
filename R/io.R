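# Readers and writers bridging external caller/phaser outputs (phased VCF,
# joint read-count TSV, CIGAR-fraction TSV) and the internal tabular model.

#' Read a joint site read-count table
#'
#' Expected format: TSV with header
#' `chrom pos ref alt <sample>_ref <sample>_alt ...`, one row per site,
#' with one `_ref`/`_alt` column pair per sample (bulk and single cells).
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_site_counts <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE,
                            col_types = readr::cols(chrom = "c"))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(counts)))
    abort("counts table must have columns chrom, pos, ref, alt")
  if (!is.numeric(counts$pos) || any(counts$pos != floor(counts$pos)) ||
      any(counts$pos < 1))
    abort("malformed coordinates in counts table")
  counts
}

count_cols <- function(counts, sample) {
  cols <- paste0(sample, c("_ref", "_alt"))
  if (!all(cols %in% names(counts)))
    abort(sprintf("sample '%s' not present in counts table", sample))
  cols
}

#' Load phase-standardized heterozygous SNPs
#'
#' Reads phased genotypes from a VCF and single-cell read counts from a
#' joint counts table, keeping phased heterozygous biallelic SNPs with
#' non-zero single-cell depth. Counts are standardized to haplotype 1: when
#' the alt allele lies on haplotype 2 (genotype `0|1`), `allele1_reads`
#' equals `depth - alt_reads`, so that AB estimates refer to a consistent
#' allele across neighboring sites.
#'
#' @param vcf_path VCF with phased genotypes (`|` separator).
#' @param counts_path Read-count TSV (see [read_site_counts()]).
#' @param sample Single-cell sample name in the counts table.
#' @param vcf_sample Genotype column to use from the VCF (default: first).
#' @return A tibble sorted by (chrom, pos) with columns `chrom`, `pos`,
#'   `ref`, `alt`, `alt_reads`, `depth`, `raw_vaf`, `hap_flip`,
#'   `allele1_reads`.
#' @export
read_phased_hsnps <- function(vcf_path, counts_path, sample,
                              vcf_sample = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fixm <- vcfR::getFIX(vcf)
  if (!is.matrix(fixm)) # single-record VCFs drop to a named vector
    fixm <- matrix(fixm, nrow = 1, dimnames = list(NULL, names(fixm)))
  fix <- as_tibble(as.data.frame(fixm, stringsAsFactors = FALSE))
  gt_mat <- vcfR::extract.gt(vcf, element = "GT")
  if (!is.matrix(gt_mat))
    gt_mat <- matrix(gt_mat, nrow = 1, dimnames = list(NULL, names(gt_mat)))
  if (is.null(vcf_sample)) vcf_sample <- colnames(gt_mat)[1]
  if (!vcf_sample %in% colnames(gt_mat))
    abort(sprintf("VCF sample '%s' not found", vcf_sample))
  sites <- tibble(chrom = fix$CHROM, pos = suppressWarnings(as.integer(fix$POS)),
                  ref = fix$REF, alt = fix$ALT, gt = unname(gt_mat[, vcf_sample]))
  if (any(is.na(sites$pos))) abort("malformed coordinates in VCF")
  multi <- grepl(",", sites$alt) | nchar(sites$ref) != 1 | nchar(sites$alt) != 1
  if (any(multi))
    warn(sprintf("skipping %d multi-allelic or non-SNP VCF records", sum(multi)))
  sites <- sites[!multi, ]
  phased_het <- sites$gt %in% c("0|1", "1|0")
  n_drop <- sum(!phased_het, na.rm = TRUE) + sum(is.na(sites$gt))
  if (n_drop > 0)
    inform(sprintf("dropped %d unphased, homozygous or missing-genotype sites",
                   n_drop))
  sites <- sites[phased_het & !is.na(sites$gt), ]
  counts <- if (is.data.frame(counts_path)) counts_path else
    read_site_counts(counts_path)
  cols <- count_cols(counts, sample)
  counts <- select(counts, "chrom", "pos",
                   ref_reads = all_of(cols[1]), alt_reads = all_of(cols[2]))
  merged <- dplyr::inner_join(sites, counts, by = c("chrom", "pos"))
  n_missing <- nrow(sites) - nrow(merged)
  if (n_missing > 0)
    warn(sprintf("%d phased VCF sites have no row in the counts table", n_missing))
  merged <- merged |>
    mutate(depth = .data$ref_reads + .data$alt_reads,
           hap_flip = .data$gt == "0|1") |>
    filter(.data$depth >= 1) |>
    mutate(raw_vaf = .data$alt_reads / .data$depth,
           allele1_reads = ifelse(.data$hap_flip,
                                  .data$depth - .data$alt_reads,
                                  .data$alt_reads)) |>
    arrange(.data$chrom, .data$pos) |>
    select("chrom", "pos", "ref", "alt", "alt_reads", "depth", "raw_vaf",
           "hap_flip", "allele1_reads")
  merged
}

#' Candidate-selection configuration
#'
#' Lenient read-support thresholds that still suppress sequencing noise:
#' a handful of variant reads in an adequately covered single cell, and a
#' covered, variant-free matched bulk (somatic candidates must be absent
#' from bulk).
#'
#' @param min_sc_depth,min_sc_alt Single-cell depth and alt-read minima.
#' @param min_bulk_depth Minimum bulk depth.
#' @param max_bulk_alt Maximum bulk alt reads.
#' @return A named list.
#' @export
candidate_config <- function(min_sc_depth = 6, min_sc_alt = 2,
                             min_bulk_depth = 10, max_bulk_alt = 0) {
  list(min_sc_depth = min_sc_depth, min_sc_alt = min_sc_alt,
       min_bulk_depth = min_bulk_depth, max_bulk_alt = max_bulk_alt)
}

#' Select candidate somatic SNVs from a joint counts table
#'
#' @param counts A counts table (path or tibble; see [read_site_counts()]).
#' @param bulk_sample,sc_sample Sample names of bulk and single cell.
#' @param config Thresholds from [candidate_config()].
#' @param hsnp_sites Optional tibble of (chrom, pos) to exclude (the phased
#'   hSNP training set; germline sites are not somatic candidates).
#' @param exclude_sites Optional additional (chrom, pos) exclusion list
#'   (e.g. population SNPs).
#' @return A tibble of candidates with columns `chrom`, `pos`, `ref`,
#'   `alt`, `sc_alt`, `sc_depth`, `bulk_alt`, `bulk_depth`, `vaf`.
#' @export
select_candidates <- function(counts, bulk_sample, sc_sample,
                              config = candidate_config(),
                              hsnp_sites = NULL, exclude_sites = NULL) {
  counts <- if (is.data.frame(counts)) counts else read_site_counts(counts)
  bc <- count_cols(counts, bulk_sample)
  sc <- count_cols(counts, sc_sample)
  out <- counts |>
    mutate(sc_alt = .data[[sc[2]]], sc_depth = .data[[sc[1]]] + .data[[sc[2]]],
           bulk_alt = .data[[bc[2]]],
           bulk_depth = .data[[bc[1]]] + .data[[bc[2]]]) |>
    filter(.data$sc_depth >= config$min_sc_depth,
           .data$sc_alt >= config$min_sc_alt,
           .data$bulk_depth >= config$min_bulk_depth,
           .data$bulk_alt <= config$max_bulk_alt) |>
    mutate(vaf = .data$sc_alt / .data$sc_depth) |>
    select("chrom", "pos", "ref", "alt", "sc_alt", "sc_depth", "bulk_alt",
           "bulk_depth", "vaf") |>
    arrange(.data$chrom, .data$pos)
  for (excl in list(hsnp_sites, exclude_sites)) {
    if (!is.null(excl) && nrow(excl) > 0) {
      n_before <- nrow(out)
      out <- anti_join(out, select(excl, "chrom", "pos"),
                       by = c("chrom", "pos"))
      if (nrow(out) < n_before)
        inform(sprintf("removed %d candidates overlapping excluded sites",
                       n_before - nrow(out)))
    }
  }
  out
}

#' Read per-site CIGAR-operation fraction profiles
#'
#' Expected format: TSV with columns `chrom pos cell_indel cell_clip
#' bulk_indel bulk_clip`, each a fraction in `[0, 1]` of reads spanning the
#' site that carry the operation type.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_cigar_profiles <- function(path) {
  prof <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(chrom = "c"))
  need <- c("chrom", "pos", "cell_indel", "cell_clip", "bulk_indel", "bulk_clip")
  if (!all(need %in% names(prof)))
    abort("CIGAR profile table must have columns chrom, pos, cell_indel, cell_clip, bulk_indel, bulk_clip")
  fr <- as.matrix(prof[, need[-(1:2)]])
  if (any(!is.finite(fr)) || any(fr < 0 | fr > 1))
    abort("CIGAR fractions must lie in [0, 1]")
  prof
}

call_tsv_path <- function(prefix) paste0(prefix, ".calls.tsv")
call_vcf_path <- function(prefix) paste0(prefix, ".calls.vcf")

#' Write genotyping results
#'
#' Writes a TSV with one row per evaluated candidate (all p-values, AB
#' posterior, tuned cutoffs, filter flags) and a VCF v4.2 containing only
#' passing calls with INFO keys `ABMU`, `ABSD`, `PABC`, `PPRE`, `PAMP`.
#'
#' @param calls A call tibble from [genotype_single()].
#' @param out_prefix Output path prefix; `<prefix>.calls.tsv` and
#'   `<prefix>.calls.vcf` are written.
#' @return Invisibly, the two paths.
#' @export
write_calls <- function(calls, out_prefix) {
  tsv <- call_tsv_path(out_prefix)
  vcf <- call_vcf_path(out_prefix)
  readr::write_tsv(as_tibble(calls), tsv)
  passing <- filter(as_tibble(calls), .data$pass)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(as_tibble(calls)$chrom), ">"),
    '##INFO=<ID=ABMU,Number=1,Type=Float,Description="Posterior mean of logit allele balance">',
    '##INFO=<ID=ABSD,Number=1,Type=Float,Description="Posterior sd of logit allele balance">',
    '##INFO=<ID=PABC,Number=1,Type=Float,Description="Allele balance consistency p-value">',
    '##INFO=<ID=PPRE,Number=1,Type=Float,Description="Pre-amplification artifact p-value">',
    '##INFO=<ID=PAMP,Number=1,Type=Float,Description="Amplification artifact p-value">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  body <- if (nrow(passing) > 0) {
    info <- sprintf("ABMU=%.6g;ABSD=%.6g;PABC=%.6g;PPRE=%.6g;PAMP=%.6g",
                    passing$mu, sqrt(passing$sigma2), passing$p_abc,
                    passing$p_preamp, passing$p_amp)
    paste(passing$chrom, passing$pos, ".", passing$ref, passing$alt, ".",
          "PASS", info, sep = "\t")
  } else character(0)
  writeLines(c(header, body), vcf)
  invisible(list(tsv = tsv, vcf = vcf))
}

#' Read back a call TSV written by [write_calls()]
#'
#' @param path Either the TSV path or the prefix passed to [write_calls()].
#' @return The call tibble (lossless round trip).
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) path <- call_tsv_path(path)
  readr::read_tsv(path, show_col_types = FALSE, na = "NA",
                  col_types = readr::cols(chrom = "c", ref = "c", alt = "c",
                                          filters = "c"))
}
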