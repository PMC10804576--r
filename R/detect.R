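#' Per-probe differential methylation by Welch's t-test
#'
#' A deliberately simple internal DMP caller so the benchmark runs
#' end-to-end: per-probe Welch two-sample t-test on beta-values followed
#' by Benjamini-Hochberg adjustment across all tested probes. Probes with
#' zero variance in both groups cannot be tested; their p-value is set to
#' 1 and they are flagged `degenerate`.
#'
#' @param beta A [beta_matrix].
#' @param groups Two-level labels per sample; defaults to
#'   `sample_meta$group`.
#' @param q_max Significance threshold on the BH-adjusted q-value.
#' @return A `data.frame` of class `dmp_table`: `probe_id`, `effect`
#'   (mean beta difference, first group level minus second in
#'   case-control order when the levels are `case`/`control`), `p_value`,
#'   `q_value`, `significant`, `degenerate`.
#' @export
dmp_ttest <- function(beta, groups = NULL, q_max = 0.05) {
  stopifnot(inherits(beta, "beta_matrix"))
  if (is.null(groups)) groups <- beta$sample_meta$group
  if (is.null(groups)) stop("no group labels supplied or found in sample_meta")
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  lev <- levels(groups)
  if (all(c("case", "control") %in% lev)) lev <- c("case", "control")
  i1 <- which(groups == lev[1])
  i2 <- which(groups == lev[2])
  if (length(i1) < 2 || length(i2) < 2) {
    stop("both groups need at least 2 samples")
  }
  x <- beta$beta
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- rowSums((x[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((x[, i2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  degenerate <- se2 == 0
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[degenerate] <- 1
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    probe_id = rownames(x), effect = m1 - m2, p_value = p, q_value = q,
    significant = q <= q_max, degenerate = degenerate,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("dmp_table", "data.frame")
  out
}

#' Merge significant probes into regions
#'
#' Significant probes on the same chromosome are merged into one region
#' while each is within `max_gap_bp` of the previous one; regions with
#' fewer than `min_probes` members are dropped.
#'
#' @param dmps A `dmp_table` from [dmp_ttest()].
#' @param ann A [probe_manifest] covering the DMP probes.
#' @param max_gap_bp Maximum distance between successive significant
#'   probes (default 702, the median CpG-island length, matching the
#'   region-construction threshold).
#' @param min_probes Minimum member probes per region (default 2).
#' @return A [region_set] of detected regions.
#' @export
dmps_to_regions <- function(dmps, ann, max_gap_bp = 702, min_probes = 2) {
  sig <- dmps$probe_id[dmps$significant]
  idx <- match(sig, ann$probe_id)
  if (anyNA(idx)) {
    stop("significant probe(s) missing from annotation: ",
         paste(utils::head(sig[is.na(idx)], 3), collapse = ", "))
  }
  if (!length(idx)) return(region_set())
  ord <- order(ann$chrom[idx], ann$pos[idx])
  idx <- idx[ord]
  chrom <- ann$chrom[idx]
  pos <- ann$pos[idx]
  brk <- chrom[-1] != chrom[-length(chrom)] | diff(pos) > max_gap_bp
  grp <- cumsum(c(TRUE, brk))
  keep <- which(tabulate(grp) >= min_probes)
  if (!length(keep)) return(region_set())
  pieces <- split(idx, grp)[as.character(keep)]
  region_set(
    chrom = vapply(pieces, function(ix) ann$chrom[ix[1]], character(1)),
    start = vapply(pieces, function(ix) ann$pos[ix[1]], integer(1)),
    end = vapply(pieces, function(ix) ann$pos[ix[length(ix)]], integer(1)),
    probes = lapply(pieces, function(ix) ann$probe_id[ix])
  )
}

#' Export a dataset for external DMP/DMR tools
#'
#' Writes the file layout external callers' wrappers expect: `beta.tsv`
#' (probes x samples), `pheno.tsv` (one row per sample: `sample_id`,
#' `group`, plus `batch` when available) and `manifest.csv`. External
#' region calls come back as BED via [read_regions_bed()].
#'
#' @param beta A [beta_matrix].
#' @param ann A [probe_manifest].
#' @param outdir Output directory (created if needed).
#' @param groups Optional group labels; defaults to
#'   `sample_meta$group`.
#' @return Invisibly, the named vector of written paths.
#' @export
export_for_external <- function(beta, ann, outdir, groups = NULL) {
  stopifnot(inherits(beta, "beta_matrix"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(groups)) groups <- beta$sample_meta$group
  pheno <- beta$sample_meta
  if (!is.null(groups)) pheno$group <- groups
  paths <- c(
    beta = file.path(outdir, "beta.tsv"),
    pheno = file.path(outdir, "pheno.tsv"),
    manifest = file.path(outdir, "manifest.csv")
  )
  write_beta_matrix(beta, paths[["beta"]])
  utils::write.table(pheno, paths[["pheno"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_manifest(ann, paths[["manifest"]])
  invisible(paths)
}
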