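---
title: "Genotyping somatic SNVs in single cells with a spatial allele-balance model"
author: "abcall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping somatic SNVs in single cells with a spatial allele-balance model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcall)
```

## The problem

Whole-genome amplification of a single cell (typically by multiple
displacement amplification, MDA) amplifies the two homologous copies of
each locus essentially independently. The result is *allelic imbalance*:
the fraction of amplified DNA derived from one allele — the allele balance
(AB) — drifts along the genome, so the variant allele fraction (VAF) of a
true heterozygous mutation can be anywhere between 0 and 1 rather than
near 50%. At the same time, physical artifacts acquired before or early
in amplification start on large fractions of the template (a
single-stranded lesion on 25% of template strands; a first-round
polymerase error on 12.5% of an idealized amplicon pool) and are then
pushed to mutation-like VAFs by the same imbalance. VAF alone therefore
cannot separate somatic SNVs from artifacts; what can is VAF *relative to
the locally estimated AB*.

`abcall` estimates AB along the genome from phased heterozygous germline
SNPs (hSNPs), tests each candidate somatic SNV (sSNV) for consistency
with the local AB and against explicit artifact models, and tunes the
artifact-test cutoffs to a user-chosen false discovery rate using an
estimate of the artifact burden.

## The latent Gaussian-process model of allele balance

At hSNP $i$ with position $X_i$, haplotype-1-supporting reads $Y_i$ and
depth $D_i$, we model

$$
Y_i \mid B_i \sim \mathrm{Bin}\!\left(D_i, \frac{1}{1+e^{-B_i}}\right),
\qquad
B \sim \mathcal{GP}(0, k),
$$

where $B$ is the logit-scale AB and the covariance function is a sum of
two squared-exponential components,

$$
k(x_1, x_2) = \exp\!\left(a - \frac{(x_1-x_2)^2}{b^2}\right)
            + \exp\!\left(c - \frac{(x_1-x_2)^2}{d^2}\right).
$$

The component with the longer length scale ($b$, bp) captures the
correlation induced by MDA amplicon size (~5–10 kb); the short-scale
component ($d$) absorbs very short-range effects such as shared reads
between neighboring sites, which would otherwise inflate the apparent
long-range correlation. Phasing matters: hSNP read counts are
standardized to a consistent haplotype (`allele1_reads`), otherwise
adjacent hSNPs on opposite haplotypes would fake abrupt AB switches.

**Fitting.** The marginal likelihood has no closed form under the
binomial observation model. Two approximations make it tractable:
(1) each chromosome is split into consecutive blocks of 100 hSNPs treated
as independent (a trailing remainder forms its own block), and (2) each
block's evidence is computed with the Laplace approximation, with the
posterior mode found by Newton–Raphson started at $B = 0$ and iterated
until the relative change of the log posterior falls below
$\sqrt{2.2\times10^{-16}}$ (at most 50 iterations). Parameters are chosen
by grid search; the default grid is
$a, c \in \{-6,-4,-2,-1,0,1\}$,
$b \in \{0.5, 1, 2, 5, 10, 20, 50\}$ kb,
$d \in \{10, 50, 150, 300, 1000\}$ bp with $d \le b$ enforced.
Fit parameters per chromosome and per cell — amplification quality
differs between cells, and correlation structure can differ between
chromosomes.

```{r fit, eval = FALSE}
hsnps <- read_phased_hsnps("phased.vcf", "counts.tsv", sample = "cellA")
fit <- fit_ab_params(dplyr::filter(hsnps, chrom == "chr1"))
glance(fit)      # selected (a, b, c, d) and its log-likelihood
autoplot(fit)    # profile likelihood over the long length scale
```

**Prediction.** AB at a candidate site is the GP posterior given the
Laplace fit of the hSNPs within ±200 kb (capped at the nearest 100 per
side for tractability; both configurable):
$\mu = k_*^\top K^{-1}\hat B$ and
$\sigma^2 = k_{**} - k_*^\top (K + W^{-1})^{-1} k_*$, where $W$ is the
binomial information at the mode. A window with no hSNPs returns the
prior ($\mu = 0$, $\sigma^2 = e^a + e^c$) and flags the site
`ab_uninformed`. The fit is redone per window rather than reusing the
fixed fitting blocks; prediction windows centered on the candidate avoid
block-boundary artifacts at the cost of a little redundant computation.

## The three genotyping tests

A mutation can sit on either allele, so the allele-balance consistency
(ABC) test first orients the posterior toward the observed VAF:
$\mu^* \in \{\mu, -\mu\}$, whichever logistic transform is nearest the
VAF (ties toward $+\mu$). The null outcome distribution marginalizes the
binomial over $B \sim N(\mu^*, \sigma^2)$ by 128-node Gauss–Hermite
quadrature, and the p-value sums all outcomes no more probable than the
observed count (equal probabilities, within $10^{-12}$, are included).
$\sigma^2 = 0$ degenerates to an exact binomial.

The artifact tests replace the success probability by the artifact's
expected allele fraction: an equal mixture over the two alleles of
$\mathrm{Bin}(D, \mathrm{AB}/f)$ and $\mathrm{Bin}(D, (1-\mathrm{AB})/f)$
with $f = 2$ for pre-amplification (single-stranded) artifacts and
$f = 4$ for first-round amplification errors. The mixture is symmetric in
$\mu$, so no orientation is needed.

A candidate **passes** when the ABC test does *not* reject it
($p_{\mathrm{ABC}} \ge 0.05$) and each artifact null *is* rejected at its
tuned cutoff ($p \le \alpha$). An artifact explanation that cannot be
rejected — including $\alpha = 0$, where no cutoff meets the FDR target —
kills the call: the site is unpowered and calling it would be
unsupported. This is deliberately conservative; in regions with AB near
2:1 a true mutation on the minor allele and a pre-amplification artifact
on the major allele both expect VAF 1/3 and are indistinguishable at any
depth, so both are (correctly) rejected. The practical consequence is
little power below VAF ≈ 40% at 30× depth.

## Artifact burden and FDR-targeted cutoffs

hSNPs and true sSNVs both start on 50% of template and feel the same
imbalance, so their VAF spectra should be similarly shaped, while
artifacts pile up at low VAF. Binning VAFs into 20 bins of width 0.05
(half-open, final bin closed), the largest plausible number of true
mutations $N_T$ is found by simulation: for a trial $N_T$, 1000
multinomial draws with the hSNP bin proportions are made, and the trial
is consistent if at least 0.5% of draws fit under the observed candidate
counts in every bin (lenient because one overfull bin in 20 already
fails a draw). The search uses a 50-point geometric grid over
$[1, \sum S]$ refined by bisection to integer resolution. Per bin,
$N_{T,i} = N_T H_i / H$ and $N_{A,i} = \max\{N_T(1 - H_i/H), 0.1\}$ — as
defined, with the 0.1 floor preventing zero FDR estimates. The procedure
runs separately per sequencing depth, pooling all sites deeper than the
hSNP 90th depth percentile; candidates at depths with no hSNPs use the
nearest hSNP depth stratum.

Given the burden $(N_{T,i,D}, N_{A,i,D})$ of a candidate's VAF bin and
depth stratum, the artifact-test cutoff is tuned per candidate: the
achievable cutoffs are the highest-density-ordered outcome sets of the
discrete artifact null (tied probabilities enter as a block, index order
breaking exact ties deterministically); for each cutoff $\alpha$ the
power $1-\beta$ to reject the artifact null is computed under the
true-mutation alternative (the ABC null at $\mu^*$), and

$$
\mathrm{FDR} \approx \frac{\alpha N_A}{\alpha N_A + (1-\beta) N_T}.
$$

The largest $\alpha$ with FDR $\le \theta$ (default target 10%) is used.
This is a guide, not formal FDR control: $N_T$ and $N_A$ are heuristics.

```{r call, eval = FALSE}
candidates <- select_candidates("counts.tsv", bulk_sample = "bulk",
                                sc_sample = "cellA", hsnp_sites = hsnps)
calls <- genotype_single(candidates, hsnps, fit$params, target_fdr = 0.1)
write_calls(calls, "cellA")
```

## Secondary filters and joint calling

Misalignment-driven artifacts tend to sit among reads with excess indel
or clipping CIGAR operations not mirrored in bulk. Given per-site
fraction tables for candidates and hSNPs, a candidate is flagged per
operation type when its single-cell fraction exceeds the 90th percentile
of the fractions at (up to 4000 randomly drawn) hSNPs whose bulk
fraction does not exceed the candidate's. The bulk-conditioned comparison
is this package's reduction of the two-dimensional (cell, bulk) empirical
distribution to a single percentile rule; when no hSNP qualifies the full
sample is used. The filter is skipped with a warning when no CIGAR
tables are supplied.

With several related cells, `joint_call()` multiplies ABC p-values over
all samples with any supporting read, penalizing a sample by 1/10 when
the GP posterior sd at the locus exceeds 1 (AB poorly determined). The
pass thresholds come from the same statistic computed at 4000 sampled
hSNPs — predicted leave-one-out, so an hSNP's own reads do not inform its
AB — grouped by supporting-sample count. A site passes when its $J$
reaches the value exceeded by 90% of hSNPs in its group: hSNPs behave
like true variants, so the threshold is set to retain 90% of them (the
quantile is configurable; a support class with no hSNP representative
inherits the nearest class's threshold). Artifact and CIGAR filters are
deliberately not applied in joint mode — recurrence across independent
amplifications is itself strong evidence against a spontaneous artifact.
Joint mode consequently has little protection against *private*
artifacts; it is a shared-mutation caller.

## QC and doublet detection

`qc_diagnostics()` compares the called-sSNV VAF spectrum against hSNPs.
When two cells are accidentally co-isolated (a doublet), sSNVs not shared
by both cells start on 25% of template and pile up near VAF 25%, while
shared ones stay hSNP-like. Binomially downsampling hSNP alt reads by
half provides the expected unshared spectrum. The doublet score is the
excess sSNV mass in VAF [0.15, 0.35] over the hSNP mass there; near 0
for a clean cell, clearly positive for a doublet.

## The simulator

`sim_dataset()` generates the structure the model assumes: hSNP positions
with exponential gaps (mean 1500 bp, the typical spacing of credible
phased hSNPs), a latent AB curve drawn exactly from the GP prior
(default truth $a=-1$, $b=10$ kb, $c=-2$, $d=150$ bp — a dominant
amplicon-scale component with overdispersed but mostly informative AB,
plus a weak sub-read-length component), truncated-Poisson depths (mean
30, matching typical whole-genome depth), and binomial reads at
role-specific fractions: carrier-allele AB for hSNPs and true sSNVs
(mutant allele assigned uniformly), half that for pre-amplification
artifacts, a quarter for amplification artifacts, and half for unshared
sSNVs in doublet mode (balanced two-cell mixing). Bulk counts are
heterozygous at hSNPs and reference-only at candidates.

What it does **not** emulate: depth waves along the genome (depths are
i.i.d.), chimeric reads, alignment artifacts, copy-number changes,
finite-genome linkage between nearby candidates, or base-quality
structure. Passing tests on simulated data therefore validate the
statistical machinery under the model's own assumptions, not robustness
to real-data pathologies such as CNVs or systematic misalignment.

## Numerical choices and test problem sizes

* Covariance matrices carry a diagonal jitter of
  $10^{-6}(e^a + e^c)$ for Cholesky stability; prior draws in the
  simulator use the same jitter (coincident positions agree to ~$10^{-3}$
  rather than exactly).
* The Laplace core follows the numerically stable
  $B = I + W^{1/2} K W^{1/2}$ factorization; the evidence includes the
  binomial normalizing constants so it approximates the full marginal
  likelihood.
* The Laplace evidence and the mode-based predictive mean carry an
  intrinsic approximation bias of order 0.005 per site at 30× depth
  (quantified against dense-grid integration in the test suite). This is
  a property of the approximation, shared by any Laplace-based
  implementation, and is immaterial to grid fitting, which compares
  evidences whose biases largely cancel across parameters.
* 128 Gauss–Hermite nodes resolve the outcome distribution to ~$10^{-6}$
  for $\sigma^2 \lesssim 1$ (the realistic posterior range); for very
  wide posteriors ($\sigma^2 = 4$) node spacing exceeds the binomial
  likelihood width and tail p-values are only accurate to ~$10^{-2}$.
  The node count is configurable; the test suite verifies convergence to
  the adaptive-quadrature value as nodes increase.
* Ties in the discrete probability orderings use a $10^{-12}$ tolerance
  and index order, applied identically in p-values and tuned cutoffs so
  the pass rule `p <= alpha` is exact.
* Test and acceptance problem sizes were chosen as the smallest that
  exercise the claims stably: parameter recovery uses 5000 hSNPs per
  seed (3 seeds); the labeled calling simulation uses 3000 hSNPs, 200
  true sSNVs and 800 artifacts at 30×; null calibration uses 2000 draws
  per depth.

## Known limitations

* Diploidy is assumed; CNVs shift AB away from the modeled regime.
* Phasing errors flip `allele1_reads` at affected sites; infrequent, and
  visible mainly in imbalanced regions.
* `estimate_nt()` is an upper-bound heuristic, not an estimator; the FDR
  targeting built on it is a stringency guide, not a guarantee.
* Joint mode passes recurrent (shared) artifacts and most private
  high-J sites in low-support classes; its output should be read as
  shared-mutation calls.
* The candidate-selection defaults (single-cell depth ≥ 6, ≥ 2 alt
  reads, bulk depth ≥ 10 with 0 alt reads) are a declared, configurable
  choice of "lenient but noise-suppressing"; appropriate values depend
  on depth and contamination.
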