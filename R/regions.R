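#' Configuration for co-methylated region discovery
#'
#' @param window Centered window size for the neighbor correlations (odd,
#'   >= 3; a probe's score averages its Pearson correlation with the
#'   `(window - 1) / 2` flanking probes on each side).
#' @param corr_threshold Mean-correlation threshold a probe must exceed
#'   (strictly) to enter a candidate region; the benchmark grid uses 0.1,
#'   0.2 and 0.4.
#' @param min_region_len_bp Minimum region span in bp; regions shorter
#'   than the minimum CpG-island length of 12 bp are discarded.
#' @param max_adjacent_gap_bp Runs are split where two adjacent probes
#'   lie further apart than the median CpG-island length of 702 bp.
#' @return A list of class `region_config`.
#' @export
region_config <- function(window = 3, corr_threshold = 0.2,
                          min_region_len_bp = 12, max_adjacent_gap_bp = 702) {
  stopifnot(
    window >= 3, window %% 2 == 1,
    corr_threshold > 0, corr_threshold < 1,
    min_region_len_bp > 0, max_adjacent_gap_bp > 0
  )
  structure(list(window = window, corr_threshold = corr_threshold,
                 min_region_len_bp = min_region_len_bp,
                 max_adjacent_gap_bp = max_adjacent_gap_bp),
            class = "region_config")
}

#' Per-probe co-methylation score
#'
#' For each probe (position-sorted within its chromosome) the score is
#' the mean Pearson correlation, computed across samples, between its
#' beta vector and those of its neighbors inside the centered window.
#' Chromosome-terminal probes use the available neighbors only.
#' Zero-variance pairings contribute 0, so constant probes score 0 and
#' never pass a positive threshold.
#'
#' @param beta A [beta_matrix] with at least 2 samples (3 or more for a
#'   meaningful correlation).
#' @param ann A [probe_manifest] covering all probes of `beta`.
#' @param cfg A [region_config].
#' @return Named numeric vector of scores in manifest `(chrom, pos)`
#'   order.
#' @export
comethylation_scores <- function(beta, ann, cfg = region_config()) {
  stopifnot(inherits(beta, "beta_matrix"))
  if (ncol(beta$beta) < 2) stop("at least 2 samples are required for correlation")
  idx <- match(ann$probe_id, rownames(beta$beta))
  if (anyNA(idx)) {
    stop("beta matrix missing probe(s): ",
         paste(utils::head(ann$probe_id[is.na(idx)], 3), collapse = ", "))
  }
  x <- beta$beta[idx, , drop = FALSE]
  half <- (cfg$window - 1) / 2
  scores <- numeric(nrow(ann))
  xc <- x - rowMeans(x)
  ss <- rowSums(xc^2)
  for (ch in unique(ann$chrom)) {
    ci <- which(ann$chrom == ch)
    p <- length(ci)
    for (j in seq_len(p)) {
      nb <- setdiff(max(1, j - half):min(p, j + half), j)
      if (!length(nb)) next
      cors <- vapply(nb, function(k) {
        den <- sqrt(ss[ci[j]] * ss[ci[k]])
        if (den == 0) 0 else sum(xc[ci[j], ] * xc[ci[k], ]) / den
      }, numeric(1))
      scores[ci[j]] <- mean(cors)
    }
  }
  names(scores) <- ann$probe_id
  scores
}

#' Build candidate co-methylated regions from probe scores
#'
#' Maximal runs of consecutive manifest probes whose score strictly
#' exceeds the threshold are split wherever two adjacent run probes lie
#' further apart than `max_adjacent_gap_bp`; surviving runs whose span
#' (`end - start + 1`) falls below `min_region_len_bp` are discarded.
#' Since a single probe spans 1 bp, every emitted region has at least two
#' member probes.
#'
#' @param scores Numeric vector of per-probe scores aligned to `ann`.
#' @param ann A [probe_manifest].
#' @param cfg A [region_config].
#' @return A sorted, non-overlapping [region_set].
#' @export
candidate_regions <- function(scores, ann, cfg = region_config()) {
  stopifnot(length(scores) == nrow(ann))
  pass <- scores > cfg$corr_threshold
  chroms <- character()
  starts <- integer()
  ends <- integer()
  probes <- list()
  for (ch in unique(ann$chrom)) {
    ci <- which(ann$chrom == ch)
    hits <- ci[pass[ci]]
    if (!length(hits)) next
    # split where passing probes are not consecutive in the manifest or
    # where the genomic gap exceeds the threshold
    brk <- diff(hits) > 1 |
      diff(ann$pos[hits]) > cfg$max_adjacent_gap_bp
    grp <- cumsum(c(TRUE, brk))
    for (g in split(hits, grp)) {
      span <- ann$pos[g[length(g)]] - ann$pos[g[1]] + 1L
      if (span < cfg$min_region_len_bp) next
      chroms <- c(chroms, ch)
      starts <- c(starts, ann$pos[g[1]])
      ends <- c(ends, ann$pos[g[length(g)]])
      probes <- c(probes, list(ann$probe_id[g]))
    }
  }
  region_set(chroms, starts, ends, probes)
}

#' Discover candidate regions directly from a beta matrix
#'
#' Convenience wrapper: [comethylation_scores()] followed by
#' [candidate_regions()].
#'
#' @inheritParams comethylation_scores
#' @return A [region_set].
#' @export
select_regions <- function(beta, ann, cfg = region_config()) {
  candidate_regions(comethylation_scores(beta, ann, cfg), ann, cfg)
}
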