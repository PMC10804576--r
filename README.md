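# dmrbench

Tissue-aware simulation of Illumina 450k-style DNA-methylation
beta-value data with known ground-truth differentially methylated
probes (DMPs) and regions (DMRs), plus the machinery to benchmark
DMP/DMR-finding workflows — normalization, batch-effect correction,
calling, scoring — against that planted truth.

It is written for methods developers and analysts who need to pick a
defensible analysis stack for a methylation study *before* the data are
in: simulate the study's context (sample size, effect magnitude, number
of altered probes), run candidate workflows against the simulated
truth, and pick the winner.

## The model in brief

Adjacent CpGs are co-methylated, so the simulator only alters probes
inside *candidate co-methylated regions*: probes are scored by the mean
Pearson correlation with their flanking neighbors (window of size 3),
runs of probes scoring above a threshold (0.1 / 0.2 / 0.4) become
regions, split where adjacent probes are > 702 bp apart and discarded
when spanning < 12 bp (the median and minimum predicted CpG-island
lengths).

For a region probe *p* and case sample *j*, the simulated beta is

```
beta'[p, j] = beta[p, j] - (mu_in(p) - b[p, j])
```

where `mu_in` is the source tissue's reference mean and `b` is drawn
from one of four approaches anchored at a *target tissue's* reference
methylome (per-probe min / mean / max beta). The flagship approach
(S4) draws `a_i ~ Beta(0.4, 0.5)` truncated to the target's
`[min, max]` bracket for within-region/between-CpG variation, averages
them, then draws `b_j ~ N(mean(a), sigma_p)` with `sigma_p` the
per-probe SD of the source data for inter-sample variation. Three
simpler approaches (deterministic shift S1, uniform cascades S2/S3) are
included for comparison. Control samples and out-of-region probes pass
through bit-identical.

The benchmark crosses cohort size (32 vs. 432 samples drawn from five
batches), target tissue difference (large vs. small reference shift)
and correlation threshold into 12 scenarios, each with a no-alteration
null twin. Region calls are scored by a 20%-overlap rule (a truth
region is recovered when detections cover > 20% of its length; a
detection is a false positive when it covers ≤ 20% of its own length of
every truth region), and the *guideline improvement* reports the
percent F1 gain of the best pipeline over the pipeline average.

## Worked example

Everything runs on synthetic data; no downloads are required.

```r
library(dmrbench)

inp <- build_benchmark_inputs(seed = 1)   # manifest, sources, references
bs  <- build_scenarios(inp$sources, inp$manifest, inp$refs, seed = 1)

sim <- bs$scenarios[["small_large_diff_thr4"]]$sim
sim
#> sim_result (S4): 2000 probes x 32 samples, 22 truth regions (88 probes)

rep <- run_benchmark(list(strong = sim), inp$manifest)
rep$table
#>   scenario_id pipeline_id    dmp_f1    dmr_f1 dmr_precision dmr_recall
#> 1      strong   none+none 0.8930818 0.9000000          1.00  0.8181818
#> 2      strong   baqn+none 0.8789809 0.8717949          1.00  0.7727273
#> 3      strong none+combat 0.9010989 0.9767442          1.00  0.9545455
#> 4      strong baqn+combat 0.6810345 0.8936170          0.84  0.9545455
rep
#> benchmark_report
#>  scenario_id best_pipeline   best_f1 improvement_pct
#>       strong   none+combat 0.9767442        7.270986
#> mean guideline improvement: 7.27%
```

Reading the output: this scenario is a small cohort (32 samples over
five batches) with a large tissue difference and the strictest region
threshold; 22 regions (88 probes) were altered. Batch correction lifts
DMR recall from 0.82 to 0.95 (the cohort is small, so batch noise
costs real power), normalization does not help, and picking the best
pipeline instead of an arbitrary one improves F1 by about 7%.

A thin command-line interface wraps the same functions
(`exec/dmrbench`): `fixtures`, `qc`, `select-regions`, `simulate`,
`normalize`, `batch-correct`, `detect`, `evaluate-dmr`.

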