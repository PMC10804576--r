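#' Quality-control configuration
#'
#' Thresholds for probe and sample filtering and for beta computation.
#' Defaults follow common 450k practice: probes failing detection
#' (p > 0.05) in any sample, probes with a negative intensity, probes on
#' common SNPs (allele frequency > 0.05) and non-specific probes are
#' excluded; samples are dropped when the log2 median intensity falls
#' below 10 in both channels; beta uses an offset of 100.
#'
#' @param detection_p_max Detection p-value threshold (default 0.05).
#' @param snp_af_max Maximum tolerated SNP allele frequency (default
#'   0.05; strict ">" excludes).
#' @param log2_median_min Minimum log2 median channel intensity (default
#'   10; a sample is removed only when *both* channels fall strictly
#'   below).
#' @param detection_fail_fraction Fraction of samples allowed to fail
#'   detection before the probe is excluded (default 0: any failure
#'   excludes).
#' @param beta_offset Offset in the beta formula `M / (M + U + offset)`.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(detection_p_max = 0.05, snp_af_max = 0.05,
                      log2_median_min = 10, detection_fail_fraction = 0,
                      beta_offset = 100) {
  stopifnot(
    detection_p_max >= 0, detection_p_max <= 1,
    snp_af_max >= 0, snp_af_max <= 1,
    detection_fail_fraction >= 0, detection_fail_fraction <= 1,
    beta_offset >= 0
  )
  structure(list(detection_p_max = detection_p_max, snp_af_max = snp_af_max,
                 log2_median_min = log2_median_min,
                 detection_fail_fraction = detection_fail_fraction,
                 beta_offset = beta_offset), class = "qc_config")
}

#' Filter low-quality probes
#'
#' Removes probes that (1) exceed the detection p-value threshold in more
#' than the allowed fraction of samples, (2) show a negative intensity in
#' either channel in any sample, (3) sit on a SNP with allele frequency
#' above the threshold, or (4) are flagged non-specific. Every removal is
#' logged with its reason(s).
#'
#' @param sig A [signal_matrix].
#' @param ann A [probe_manifest] covering every probe in `sig`.
#' @param cfg A [qc_config].
#' @return A list with `signals` (the filtered [signal_matrix]) and
#'   `removed`, a `data.frame` of `probe_id` and comma-joined `reason`.
#' @export
filter_probes <- function(sig, ann, cfg = qc_config()) {
  stopifnot(inherits(sig, "signal_matrix"))
  idx <- match(rownames(sig$M), ann$probe_id)
  if (anyNA(idx)) {
    stop("probe(s) missing from annotation: ",
         paste(utils::head(rownames(sig$M)[is.na(idx)], 3), collapse = ", "))
  }
  ann <- ann[idx, , drop = FALSE]
  n_samp <- ncol(sig$M)
  fail_frac <- rowMeans(sig$detection_p > cfg$detection_p_max)
  det <- fail_frac > cfg$detection_fail_fraction
  neg <- rowSums(sig$M < 0 | sig$U < 0) > 0
  snp <- !is.na(ann$snp_af) & ann$snp_af > cfg$snp_af_max
  nonspec <- ann$nonspecific
  reasons <- cbind(detection = det, `negative intensity` = neg,
                   snp = snp, nonspecific = nonspec)
  drop <- rowSums(reasons) > 0
  removed <- data.frame(
    probe_id = rownames(sig$M)[drop],
    reason = apply(reasons[drop, , drop = FALSE], 1, function(r) {
      paste(colnames(reasons)[r], collapse = ",")
    }),
    stringsAsFactors = FALSE
  )
  rownames(removed) <- NULL
  keep <- !drop
  list(
    signals = signal_matrix(sig$M[keep, , drop = FALSE],
                            sig$U[keep, , drop = FALSE],
                            sig$detection_p[keep, , drop = FALSE]),
    removed = removed
  )
}

#' Filter low-quality samples
#'
#' A sample is removed only when its log2 median intensity is strictly
#' below the threshold in *both* the methylated and unmethylated
#' channels.
#'
#' @param sig A non-empty [signal_matrix].
#' @param cfg A [qc_config].
#' @return A list with `signals` (the filtered [signal_matrix]) and
#'   `removed`, a `data.frame` of `sample_id`, `log2_median_m`,
#'   `log2_median_u`.
#' @export
filter_samples <- function(sig, cfg = qc_config()) {
  stopifnot(inherits(sig, "signal_matrix"), ncol(sig$M) > 0)
  lm <- suppressWarnings(log2(apply(sig$M, 2, stats::median)))
  lu <- suppressWarnings(log2(apply(sig$U, 2, stats::median)))
  lm[is.nan(lm)] <- -Inf
  lu[is.nan(lu)] <- -Inf
  drop <- lm < cfg$log2_median_min & lu < cfg$log2_median_min
  if (all(drop)) stop("sample QC removed every sample")
  removed <- data.frame(sample_id = colnames(sig$M)[drop],
                        log2_median_m = lm[drop], log2_median_u = lu[drop],
                        stringsAsFactors = FALSE)
  rownames(removed) <- NULL
  keep <- !drop
  list(
    signals = signal_matrix(sig$M[, keep, drop = FALSE],
                            sig$U[, keep, drop = FALSE],
                            sig$detection_p[, keep, drop = FALSE]),
    removed = removed
  )
}

#' Compute beta-values from channel intensities
#'
#' `beta = M / (M + U + offset)`; with the conventional offset of 100 the
#' ratio is shrunk towards 0 at low total intensity and is defined even
#' when both channels read zero.
#'
#' @param sig A [signal_matrix] that has passed QC (non-negative
#'   intensities).
#' @param cfg A [qc_config]; `beta_offset` is used.
#' @param sample_meta Optional sample metadata forwarded to the result.
#' @return A [beta_matrix] of the same shape.
#' @export
compute_beta <- function(sig, cfg = qc_config(), sample_meta = NULL) {
  stopifnot(inherits(sig, "signal_matrix"))
  beta <- sig$M / (sig$M + sig$U + cfg$beta_offset)
  beta[sig$M == 0 & sig$U == 0 & cfg$beta_offset == 0] <- 0
  beta_matrix(beta, sample_meta = sample_meta)
}
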