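#' Between-array quantile normalization of beta-values
#'
#' Within each probe stratum, every sample's values are replaced so that
#' all samples share the stratum-wise reference distribution (the mean of
#' the sorted columns); ranks within each sample are preserved and ties
#' receive the average of the tied quantiles. Unstratified, this is plain
#' between-array quantile normalization of beta-values (BetaQN); with
#' `strata = design type` it is the stratified variant (BAQN) that
#' normalizes Infinium type I and type II probes separately, respecting
#' their different intensity chemistry.
#'
#' @param beta A [beta_matrix] with at least 2 samples.
#' @param strata Optional factor/character vector over probes (e.g. the
#'   manifest's `design_type` aligned to the probe order), or `NULL` for
#'   a single stratum.
#' @return A [beta_matrix] of the same shape and metadata.
#' @export
quantile_normalize <- function(beta, strata = NULL) {
  stopifnot(inherits(beta, "beta_matrix"))
  if (ncol(beta$beta) < 2) stop("quantile normalization needs at least 2 samples")
  x <- beta$beta
  if (is.null(strata)) strata <- rep("all", nrow(x))
  if (length(strata) != nrow(x)) {
    stop("'strata' must have one entry per probe")
  }
  out <- x
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < 2) {
      warning(sprintf("stratum '%s' has fewer than 2 probes; left unchanged", s))
      next
    }
    out[idx, ] <- limma::normalizeQuantiles(x[idx, , drop = FALSE], ties = TRUE)
  }
  beta_matrix(pmin(pmax(out, 0), 1), beta$sample_meta)
}

#' Stratified quantile normalization by probe design type
#'
#' Convenience wrapper running [quantile_normalize()] with the manifest's
#' design type as strata.
#'
#' @param beta A [beta_matrix].
#' @param ann A [probe_manifest] covering the probes of `beta`.
#' @return A [beta_matrix].
#' @export
baqn <- function(beta, ann) {
  idx <- match(rownames(beta$beta), ann$probe_id)
  if (anyNA(idx)) stop("manifest does not cover all probes")
  quantile_normalize(beta, strata = ann$design_type[idx])
}

#' Normalization evaluation metrics
#'
#' Four metrics compare normalization outputs: the median over all / type
#' I / type II probes of the per-probe SD across samples (technical
#' variability; lower is better), and `dmrse`, the standard error across
#' samples of the mean beta over a fixed set of imprinted-DMR probes
#' whose methylation should be tightly controlled (lower is better).
#'
#' @param beta A [beta_matrix].
#' @param ann A [probe_manifest] covering the probes of `beta`.
#' @param idmr_probes Character vector of imprinted-DMR probe ids present
#'   in `beta`.
#' @param method Label stored in the report.
#' @return A list of class `norm_report` with `method`,
#'   `median_probe_sd_all`, `median_probe_sd_type1`,
#'   `median_probe_sd_type2`, `dmrse`.
#' @export
norm_metrics <- function(beta, ann, idmr_probes, method = "unnamed") {
  stopifnot(inherits(beta, "beta_matrix"))
  idx <- match(rownames(beta$beta), ann$probe_id)
  if (anyNA(idx)) stop("manifest does not cover all probes")
  dt <- ann$design_type[idx]
  sds <- apply(beta$beta, 1, stats::sd)
  dmrse <- NA_real_
  if (length(idmr_probes) == 0) {
    warning("empty iDMR probe set; dmrse undefined")
  } else {
    if (!all(idmr_probes %in% rownames(beta$beta))) {
      stop("iDMR probe(s) missing from the beta matrix")
    }
    per_sample <- colMeans(beta$beta[idmr_probes, , drop = FALSE])
    dmrse <- stats::sd(per_sample) / sqrt(ncol(beta$beta))
  }
  structure(list(
    method = method,
    median_probe_sd_all = stats::median(sds),
    median_probe_sd_type1 = stats::median(sds[dt == "I"]),
    median_probe_sd_type2 = stats::median(sds[dt == "II"]),
    dmrse = dmrse
  ), class = "norm_report")
}

#' @export
print.norm_report <- function(x, ...) {
  cat(sprintf(
    "norm_report [%s]: sd(all)=%.4g sd(I)=%.4g sd(II)=%.4g dmrse=%.4g\n",
    x$method, x$median_probe_sd_all, x$median_probe_sd_type1,
    x$median_probe_sd_type2, x$dmrse
  ))
  invisible(x)
}

#' Empirical-Bayes batch-effect correction of beta-values
#'
#' Parametric location/scale adjustment (ComBat): per-probe
#' standardization against a group-covariate linear fit, empirical-Bayes
#' shrinkage of per-batch location and scale, and back-transformation.
#' Runs directly on beta-values; the output is clamped back into
#' `[0, 1]`.
#'
#' @param beta A [beta_matrix].
#' @param batch Batch labels per sample; defaults to
#'   `sample_meta$batch`.
#' @param group Biological group labels per sample retained as a
#'   covariate; defaults to `sample_meta$group` when present.
#' @return A corrected [beta_matrix] of the same shape and metadata.
#' @export
batch_correct <- function(beta, batch = NULL, group = NULL) {
  stopifnot(inherits(beta, "beta_matrix"))
  if (is.null(batch)) batch <- beta$sample_meta$batch
  if (is.null(batch)) stop("no batch labels supplied or found in sample_meta")
  if (is.null(group)) group <- beta$sample_meta$group
  batch <- as.factor(batch)
  if (nlevels(batch) < 2) stop("batch correction needs at least 2 batches")
  if (any(table(batch) < 2)) stop("every batch needs at least 2 samples")
  mod <- NULL
  if (!is.null(group)) {
    group <- as.factor(group)
    if (nlevels(group) > 1) {
      per_batch <- tapply(group, batch, function(g) length(unique(g)))
      if (any(per_batch < 2)) {
        stop("batch and group are confounded: a batch contains only one group")
      }
      mod <- stats::model.matrix(~group)
    }
  }
  dump <- utils::capture.output(corrected <- suppressMessages(
    sva::ComBat(dat = beta$beta, batch = batch, mod = mod,
                par.prior = TRUE, prior.plots = FALSE)
  ))
  beta_matrix(pmin(pmax(corrected, 0), 1), beta$sample_meta)
}
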