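# Small shared fixture builders for the unit tests.

tiny_manifest <- function(pos, chrom = "chr1", design = NULL) {
  n <- length(pos)
  if (is.null(design)) design <- rep(c("I", "II"), length.out = n)
  probe_manifest(data.frame(
    probe_id = sprintf("cg%05d", seq_len(n)),
    chrom = rep(chrom, length.out = n),
    pos = as.integer(pos),
    design_type = design,
    stringsAsFactors = FALSE
  ))
}

tiny_beta <- function(mat, groups = NULL, batch = NULL) {
  rownames(mat) <- sprintf("cg%05d", seq_len(nrow(mat)))
  colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  meta <- data.frame(sample_id = colnames(mat), stringsAsFactors = FALSE)
  if (!is.null(groups)) meta$group <- groups
  if (!is.null(batch)) meta$batch <- batch
  beta_matrix(mat, meta)
}

flat_reference <- function(probe_ids, mean_beta, halfwidth = 0.05,
                           tissue = "tissue") {
  mu <- rep_len(mean_beta, length(probe_ids))
  reference_profile(tissue, probe_ids,
                    min_beta = pmax(0, mu - halfwidth),
                    mean_beta = mu,
                    max_beta = pmin(1, mu + halfwidth))
}

flat_stats <- function(probe_ids, sd_beta = 0.02) {
  source_stats(data.frame(probe_id = probe_ids,
                          sd_beta = rep_len(sd_beta, length(probe_ids)),
                          stringsAsFactors = FALSE))
}
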