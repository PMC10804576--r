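Package: dmrbench
Title: Tissue-Aware Simulation and Benchmarking of Differential
    Methylation Analysis Workflows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Illumina 450k-style DNA-methylation beta-value
    datasets with known ground-truth differentially methylated probes and
    regions by anchoring altered probes to a target-tissue reference
    methylome, and benchmarks differentially-methylated-position and
    -region detection workflows (normalization, batch-effect correction,
    calling) against that planted truth. Includes probe/sample quality
    control, co-methylated region discovery by windowed Pearson
    correlation, stratified between-array quantile normalization,
    empirical-Bayes batch correction, interval-overlap scoring of region
    calls, and a deterministic synthetic-data generator so the full
    pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    limma,
    sva,
    e1071,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
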