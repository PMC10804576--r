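---
title: "Simulating tissue-aware methylation data and benchmarking DMP/DMR workflows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating tissue-aware methylation data and benchmarking DMP/DMR workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrbench)
```

## The problem

Differentially methylated positions (DMPs) and regions (DMRs) are the
workhorse readout of Illumina 450k-style methylation arrays, but the
analysis stack in front of the caller — normalization, batch-effect
correction, the caller itself — is a maze of defensible choices whose
best combination depends on the study context: how many samples there
are, how large the case–control methylation difference is, and how many
probes it touches. Benchmarking those choices requires datasets with
*known* truth, and simulated methylation data is only informative if it
reproduces two stubborn properties of the real thing: adjacent CpGs are
co-methylated, and per-probe variation differs between samples and
between CpGs.

`dmrbench` implements a tissue-aware simulator built on that
observation, plus the scaffolding to benchmark whole workflows against
the simulated truth. Instead of injecting arbitrary shifts, the
simulator anchors altered probes to a *target tissue's* reference
methylome (per-probe minimum / mean / maximum beta, as published in
tissue reference compendia), so simulated "cases" drift towards a real
biological state rather than towards noise.

## The simulation model

Candidate regions are discovered in the source data by co-methylation:
probes are sorted by genomic position, each probe is scored with the
mean Pearson correlation (across samples) to its neighbors in a
centered window of size 3, and maximal runs of probes whose score
exceeds a threshold (0.1, 0.2 or 0.4) become candidate regions. Two
CpG-island-derived filters clean them up: runs are split where adjacent
probes lie more than 702 bp apart (the median predicted island length)
and regions spanning less than 12 bp (the minimum island length) are
dropped. The window is interpreted as the probe's two immediate
flanking neighbors; chromosome-terminal probes use the neighbor they
have; zero-variance probes score 0 and can never pass a positive
threshold.

For a region probe $p$ and case sample $j$, the simulated value is

$$\beta'_{p,j} = \beta_{p,j} - \left(\mu_{\mathrm{in}}(p) - b_{p,j}\right),$$

where $\mu_{\mathrm{in}}$ is the source (input) tissue's reference mean
and $b_{p,j}$ is an approach-specific draw anchored at the target
tissue's reference:

* **S1**: $b = \mu_{\mathrm{tg}}(p)$ — a deterministic shift by the
  reference-mean difference (the naive baseline).
* **S2**: a per-probe average of $n$ uniform draws on
  $[\min_{\mathrm{tg}}, \max_{\mathrm{tg}}]$, then per-sample uniforms
  around that average.
* **S3**: per-sample normals $b_j \sim \mathcal N(m_p, \sigma_p)$ with
  $\sigma_p$ the per-probe SD of the source data. The center $m_p$ is
  the target reference mean by default (`s3_mode = "equation"`); an
  alternative mode (`"text"`) centers on a per-probe average of uniform
  draws instead, since both parameterizations are defensible
  descriptions of a uniform-then-normal cascade.
* **S4**: per-probe draws $a_i \sim \mathrm{Beta}(0.4, 0.5)$ truncated
  to $[\min_{\mathrm{tg}}, \max_{\mathrm{tg}}]$ (within-region,
  between-CpG variation), averaged to $\bar a_p$, then
  $b_j \sim \mathcal N(\bar a_p, \sigma_p)$ (inter-sample variation).

Truncated Beta draws use the inverse-CDF transform on
$[F(\mathrm{lo}), F(\mathrm{hi})]$, which is exact and cheap.
Subtraction can push values out of $[0,1]$; the model itself is silent
about this, so results are clamped to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$
(configurable). Everything the simulator does not touch — control
samples, probes outside candidate regions — is returned bit-identical
to the input, which the tests assert exactly. S1 with identical
source/target references is a global identity, and S3 in equation mode
collapses onto S1 as $\sigma \to 0$.

Choices that were genuinely open and how we resolved them:

* The first-stage uniform/Beta draws are made per probe and averaged
  (the two-stage cascade passes "the average beta-value for each probe"
  to the second stage); the second-stage draws are per (probe, case
  sample).
* S2's second uniform has no stated support; we center it on the
  first-stage average with half-width $\sqrt 3\,\sigma_p$, so its SD
  equals $\sigma_p$ and S2 is variance-matched to S3/S4, truncated to
  $[0,1]$.
* Odd per-batch sample counts split with cases taking
  $\lfloor n/2 \rfloor$.

## The benchmark grid

The benchmark crosses three context axes into 12 scenarios:

* **cohort size**: small ($14+6+4+4+4 = 32$ samples) or large
  ($204+156+31+17+24 = 432$), drawn from five batches with these fixed
  per-batch counts;
* **tissue difference**: a large-shift or a small-shift target
  reference (how far cases move);
* **correlation threshold**: 0.1 / 0.2 / 0.4 (how many probes are
  altered — looser thresholds select more probes).

Within every batch, half the samples (floor) become cases. Each
scenario ships with a *null twin*: the identical case/control split
with no probe altered, which pins the false-positive behaviour of any
downstream caller. Region discovery is run on the largest single batch
of the source data: batch effects on arrays are probe-specific location
shifts, and computing cross-sample correlations on a batch mixture
would let those shifts masquerade as co-methylation.

## Preprocessing and detection

Between-array quantile normalization maps every sample's values onto
the mean-of-sorted-columns reference distribution, either in one pool
(BetaQN) or separately within Infinium type I and type II probe strata
(BAQN), the stratification reflecting the two probe chemistries'
different intensity distributions. Normalization outputs are compared
with four metrics: the median per-probe SD across samples (over all /
type I / type II probes) and `dmrse`, the standard error across samples
of the mean beta over a fixed imprinted-DMR probe set, whose
methylation should be invariant. Batch correction is the parametric
empirical-Bayes location/scale model (ComBat, via the `sva` package)
run directly on beta-values with the case/control label as a protected
covariate, and the output clamped back to $[0,1]$.

The internal DMP caller is deliberately plain — per-probe Welch t-test
with Benjamini–Hochberg adjustment, adjacency-merged into regions
(significant probes within 702 bp, at least 2 probes per region) — so
that the benchmark machinery runs end-to-end with no external tools;
published callers plug in through a file-based adapter
(`export_for_external()` writes the beta/phenotype/manifest layout,
their region calls come back as BED).

## Evaluation

Probe-level evaluation is the standard confusion table over the tested
probe universe, with 0/0 rates reported as undefined rather than 0. At
the region level there is no negative universe, so scoring follows a
20%-overlap rule: a truth region is a TP when the total detected
overlap strictly exceeds 20% of *its* length, else an FN; a detected
region is an FP when its overlap with every single truth region is at
most 20% of the *detected* length. The wording of the rule fixes the
truth-side denominator; the FP-side denominator (detected length,
strict inequality to escape) is our reading, and at an exact 20% tie a
detection can simultaneously confirm a truth region and count as an FP
— the boundary test pins this behaviour. Multiple detections covering
one truth region pool their overlap for the TP test; each detection is
assessed once.

Per-scenario workflow selection ranks pipelines by DMR F1, and the
*guideline improvement* is the percent gain of the selected pipeline
over the mean of all pipelines for that input. Truth regions can be
stratified by realized effect (mean absolute case–control difference
over member probes, threshold 0.3) to ask whether conclusions differ
for large- and small-effect DMRs.

Two simulator-validation views are included. `pca_dispersion()` fits
PCA on the pooled samples and returns the Euclidean distance between
group centroids in the first $k$ components ($k = 2$ by default); the
underlying dispersion notion was never given a formula, so centroid
distance — monotone in any reasonable notion of group separation — is
our definition, and it is zero exactly for identical groups.
`svm_eval()` follows the classification protocol: stratified 80/20
split of real multi-tissue samples, PCA fitted on the training split
only, a linear-kernel SVM on the first 10 components with 10-fold
cross-validation, test and simulated samples projected into the trained
space, and the mean absolute decision value over simulated samples as
the score (the kernel was unspecified; linear is the natural choice on
PC coordinates, which are left unscaled so that pure-noise components
cannot dominate).

## The synthetic-data generator

All tests and the acceptance script run on synthetic data emulating
every external input:

* **manifest** — probes laid out per chromosome with exponential gaps
  (mean 500 bp, so a realistic share exceed the 702 bp split
  threshold), a 450k-like type I/II mix, and exact fractions of
  SNP-flagged and non-specific probes;
* **source beta data** — per-probe baseline means from a mildly bimodal
  Beta(0.85, 0.85) (methylation is bimodal genome-wide), logit-scale
  observation noise (SD 0.35), probe-specific per-batch offsets (SD 0.8
  on the logit scale — additive on logit keeps values in (0,1) and
  mimics multiplicative intensity bias), and a shared per-region,
  per-sample latent factor (weight 0.9) that produces the
  co-methylation signal region discovery expects;
* **reference profiles** — the same baseline methylome with the target
  mean shifted by a configurable $\Delta$ inside designated regions
  (0.35 for the "large difference" target, 0.12 for the "small
  difference" one, straddling the 0.3 effect-stratification threshold
  the way two real tissues of different relatedness would) and min/max
  bracketing each mean at $\pm 0.05$;
* **signal intensities** — two channels consistent with a planted beta
  at total intensity 4000 and offset 100, with optional planted defects
  (failed detection p-values, negative intensities, whole samples with
  depressed medians) that the QC module must recover exactly.

What the generator does *not* emulate: genome-scale probe density (the
default is 2,000 probes over two chromosomes — large enough for stable
rank statistics and multi-region structure, small enough that the whole
suite runs in seconds), type-I/II intensity-distribution differences
(strata are labels, not different chemistries, so BAQN-vs-BetaQN
comparisons on fixtures test mechanics rather than biology),
cell-type-composition heterogeneity, and probe-wise SD structure beyond
the logit-noise model. Green tests therefore certify the machinery and
the model's internal guarantees — conservation, seeded determinism,
planted-truth recovery under the stated noise — not performance on any
particular real cohort.

## Worked example

```{r, eval = FALSE}
library(dmrbench)

inp <- build_benchmark_inputs(seed = 1)
bs <- build_scenarios(inp$sources, inp$manifest, inp$refs, seed = 1)
bs

sim <- bs$scenarios[["small_large_diff_thr4"]]$sim
rep <- run_benchmark(list(strong = sim), inp$manifest)
rep
```

Numerical conventions worth knowing: thresholds are strict (`>`) for
region membership, detection-p failure, and the SNP allele-frequency
cut, matching each rule's phrasing ("more than"); the sample filter
removes a sample only when *both* channels sit strictly below the
log2-median cut of 10; the beta formula's offset (100) is the platform
convention and is configurable; and every random step — fixtures,
case/control splits, simulator draws — is governed by an explicit seed,
so identical configurations reproduce bit-identical outputs.
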