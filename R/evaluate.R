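#' Overlap-scoring configuration
#'
#' @param min_overlap_fraction A detected/truth pairing must exceed this
#'   fraction (strictly) of the relevant region's length to count
#'   (default 0.2).
#' @param fold_change_threshold Per-region mean absolute beta difference
#'   separating large-effect from small-effect regions (default 0.3).
#' @return A list of class `overlap_config`.
#' @export
overlap_config <- function(min_overlap_fraction = 0.2,
                           fold_change_threshold = 0.3) {
  stopifnot(min_overlap_fraction > 0, min_overlap_fraction < 1,
            fold_change_threshold > 0, fold_change_threshold < 1)
  structure(list(min_overlap_fraction = min_overlap_fraction,
                 fold_change_threshold = fold_change_threshold),
            class = "overlap_config")
}

#' Probe-level (DMP) confusion evaluation
#'
#' Compares predicted against true differentially methylated probes over
#' a common probe universe: `TP = |truth & pred|`, `FP = |pred \ truth|`,
#' `FN = |truth \ pred|`, `TN = |universe \ (truth | pred)|`, with the
#' standard derived rates. Undefined ratios are reported as `NA`.
#'
#' @param truth_probes,predicted_probes Character vectors, both subsets
#'   of `universe`.
#' @param universe Character vector of all tested probe ids.
#' @return An [eval_report] with TN defined.
#' @export
dmp_eval <- function(truth_probes, predicted_probes, universe) {
  truth_probes <- unique(truth_probes)
  predicted_probes <- unique(predicted_probes)
  universe <- unique(universe)
  if (!all(truth_probes %in% universe)) stop("truth probes outside the universe")
  if (!all(predicted_probes %in% universe)) {
    stop("predicted probes outside the universe")
  }
  tp <- length(intersect(truth_probes, predicted_probes))
  fp <- length(setdiff(predicted_probes, truth_probes))
  fn <- length(setdiff(truth_probes, predicted_probes))
  tn <- length(universe) - tp - fp - fn
  eval_report(tp, fp, fn, tn)
}

#' Region-level (DMR) evaluation by the 20%-overlap rule
#'
#' Each truth region is a TP when the total overlap contributed by
#' detected regions strictly exceeds `min_overlap_fraction` of the truth
#' region's length, otherwise an FN. Each detected region is an FP when
#' its overlap with every single truth region is at most
#' `min_overlap_fraction` of the *detected* region's length. There is no
#' region universe, so TN (and specificity) are undefined at the region
#' level.
#'
#' @param truth,detected [region_set]s on the same coordinate system
#'   (regions non-overlapping within each set).
#' @param cfg An [overlap_config].
#' @return An [eval_report] with `tn = NA`.
#' @export
dmr_eval <- function(truth, detected, cfg = overlap_config()) {
  stopifnot(inherits(truth, "region_set"), inherits(detected, "region_set"))
  frac <- cfg$min_overlap_fraction
  if (nrow(truth) > 0 && nrow(detected) > 0 &&
      any(grepl("^chr", truth$chrom)) != any(grepl("^chr", detected$chrom))) {
    stop("mixed chromosome naming between truth and detected sets")
  }
  truth_hit <- rep(FALSE, nrow(truth))
  det_ok <- rep(FALSE, nrow(detected))
  truth_cov <- rep(0L, nrow(truth))
  chroms <- union(truth$chrom, detected$chrom)
  for (ch in chroms) {
    ti <- which(truth$chrom == ch)
    di <- which(detected$chrom == ch)
    if (!length(ti) || !length(di)) next
    tr <- IRanges::IRanges(truth$start[ti], truth$end[ti])
    dr <- IRanges::IRanges(detected$start[di], detected$end[di])
    ov <- IRanges::findOverlaps(tr, dr)
    if (!length(ov)) next
    w <- IRanges::width(IRanges::pintersect(
      tr[S4Vectors::queryHits(ov)], dr[S4Vectors::subjectHits(ov)]
    ))
    # pooled coverage per truth region
    cov_by_truth <- tapply(w, S4Vectors::queryHits(ov), sum)
    truth_cov[ti[as.integer(names(cov_by_truth))]] <-
      truth_cov[ti[as.integer(names(cov_by_truth))]] + as.integer(cov_by_truth)
    # best single-truth overlap per detected region
    best_by_det <- tapply(w, S4Vectors::subjectHits(ov), max)
    dj <- di[as.integer(names(best_by_det))]
    det_len <- detected$end[dj] - detected$start[dj] + 1
    det_ok[dj] <- det_ok[dj] | (as.numeric(best_by_det) > frac * det_len)
  }
  truth_len <- truth$end - truth$start + 1
  truth_hit <- truth_cov > frac * truth_len
  tp <- sum(truth_hit)
  fn <- sum(!truth_hit)
  fp <- sum(!det_ok)
  eval_report(tp, fp, fn, NA_integer_)
}

#' Partition truth regions by realized effect size
#'
#' A region's effect is the mean over member probes of the absolute
#' difference in group means (|mean(case) - mean(control)|). Regions with
#' effect strictly above `fold_change_threshold` form the large-effect
#' set; the rest the small-effect set.
#'
#' @param truth A [region_set].
#' @param sim A `sim_result` (or any [beta_matrix] with `group` metadata)
#'   containing case and control samples for all truth probes.
#' @param cfg An [overlap_config].
#' @return A list with `large` and `small` [region_set]s and the numeric
#'   `effects` vector.
#' @export
stratify_regions_by_effect <- function(truth, sim, cfg = overlap_config()) {
  beta <- if (inherits(sim, "sim_result")) sim$beta else sim
  stopifnot(inherits(beta, "beta_matrix"))
  grp <- beta$sample_meta$group
  ci <- which(grp == "case")
  ki <- which(grp == "control")
  if (!length(ci) || !length(ki)) stop("need both case and control samples")
  effects <- vapply(seq_len(nrow(truth)), function(r) {
    p <- truth$probes[[r]]
    if (!all(p %in% rownames(beta$beta))) {
      stop("region probe(s) missing from the beta matrix")
    }
    mean(abs(rowMeans(beta$beta[p, ci, drop = FALSE]) -
               rowMeans(beta$beta[p, ki, drop = FALSE])))
  }, numeric(1))
  big <- effects > cfg$fold_change_threshold
  sub <- function(keep) {
    region_set(truth$chrom[keep], truth$start[keep], truth$end[keep],
               truth$probes[keep])
  }
  list(large = sub(big), small = sub(!big), effects = effects)
}

#' Percent F1 improvement of a selected pipeline over the average
#'
#' `100 * (F1_selected - mean(F1_all)) / mean(F1_all)`: how much the
#' context-specific guideline choice gains over running an arbitrary
#' pipeline for the same input.
#'
#' @param f1_by_pipeline Named numeric vector of F1 scores (>= 2
#'   pipelines).
#' @param selected_pipeline Name of the guideline-selected pipeline.
#' @return Percent improvement (scalar), `NA` with a warning when the
#'   mean F1 is 0.
#' @export
guideline_improvement <- function(f1_by_pipeline, selected_pipeline) {
  if (length(f1_by_pipeline) < 2) stop("need at least 2 pipelines")
  if (!selected_pipeline %in% names(f1_by_pipeline)) {
    stop("selected pipeline not among the scored pipelines")
  }
  m <- mean(f1_by_pipeline)
  if (m == 0) {
    warning("mean F1 is 0; improvement undefined")
    return(NA_real_)
  }
  100 * (f1_by_pipeline[[selected_pipeline]] - m) / m
}

as_sample_matrix <- function(x) {
  if (inherits(x, "beta_matrix")) x$beta else as.matrix(x)
}

#' PCA dispersion between two sample groups
#'
#' PCA is fitted on the combined samples; the score is the Euclidean
#' distance between the two group centroids in the first `k` principal
#' coordinates. Used three ways to judge a simulator: simulated vs. real
#' target tissue (lower is better), simulated vs. source tissue (higher
#' is better), and simulated-plus-target vs. source groups (higher is
#' better).
#'
#' @param groupA,groupB [beta_matrix] objects or probes-x-samples
#'   matrices over the same probes.
#' @param k Number of principal components (default 2).
#' @return Non-negative dispersion score.
#' @export
pca_dispersion <- function(groupA, groupB, k = 2) {
  a <- as_sample_matrix(groupA)
  b <- as_sample_matrix(groupB)
  stopifnot(nrow(a) == nrow(b))
  comb <- t(cbind(a, b))
  pr <- stats::prcomp(comb, center = TRUE, scale. = FALSE)
  if (k > ncol(pr$x)) {
    stop(sprintf("k = %d exceeds the %d available components", k, ncol(pr$x)))
  }
  sc <- pr$x[, seq_len(k), drop = FALSE]
  na <- ncol(a)
  ca <- colMeans(sc[seq_len(na), , drop = FALSE])
  cb <- colMeans(sc[-seq_len(na), , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}

#' SVM tissue-classification check of simulated data
#'
#' Real samples of several tissues are split 80/20 (stratified); PCA is
#' fitted on the training samples only and an SVM (linear kernel) is
#' trained on their first `k` principal components with `folds`-fold
#' cross-validation. Test and simulated samples are projected into the
#' trained PC space and classified. The mean absolute SVM decision value
#' over the simulated samples summarizes how confidently they land in
#' their intended class; higher is better.
#'
#' @param train A [beta_matrix] (or matrix) of real samples.
#' @param labels Tissue label per training sample (>= 3 classes, each
#'   with at least `folds` samples).
#' @param simulated A [beta_matrix] (or matrix) of simulated samples over
#'   the same probes.
#' @param k Number of principal components (default 10).
#' @param split Training fraction (default 0.8).
#' @param folds Cross-validation folds (default 10).
#' @param seed RNG seed for the split.
#' @return A list of class `svm_eval_report`: `train_accuracy` (CV
#'   accuracy on the training split), `test_accuracy`,
#'   `mean_abs_decision`, `sim_predicted`.
#' @export
svm_eval <- function(train, labels, simulated, k = 10, split = 0.8,
                     folds = 10, seed = 1) {
  x <- as_sample_matrix(train)
  s <- as_sample_matrix(simulated)
  labels <- as.factor(labels)
  stopifnot(ncol(x) == length(labels), nrow(x) == nrow(s))
  if (nlevels(labels) < 3) stop("at least 3 classes are required")
  if (any(table(labels) < folds)) {
    stop("every class needs at least as many samples as CV folds")
  }
  set.seed(seed)
  tr_idx <- sort(unlist(lapply(split(seq_along(labels), labels), function(ix) {
    sample(ix, max(1, round(split * length(ix))))
  }), use.names = FALSE))
  te_idx <- setdiff(seq_along(labels), tr_idx)
  xt <- t(x[, tr_idx, drop = FALSE])
  pr <- stats::prcomp(xt, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pr$x))
  project <- function(mat) {
    sweep(t(mat), 2, pr$center) %*% pr$rotation[, seq_len(k), drop = FALSE]
  }
  ptrain <- pr$x[, seq_len(k), drop = FALSE]
  # PC coordinates already carry the eigenvalue weighting; rescaling them
  # to unit variance would let pure-noise components dominate
  fit <- e1071::svm(ptrain, labels[tr_idx], kernel = "linear", cross = folds,
                    scale = FALSE)
  test_acc <- NA_real_
  if (length(te_idx)) {
    pred_te <- stats::predict(fit, project(x[, te_idx, drop = FALSE]))
    test_acc <- mean(pred_te == labels[te_idx])
  }
  psim <- project(s)
  pred_sim <- stats::predict(fit, psim, decision.values = TRUE)
  dec <- attr(pred_sim, "decision.values")
  structure(list(
    train_accuracy = fit$tot.accuracy / 100,
    test_accuracy = test_acc,
    mean_abs_decision = mean(abs(dec)),
    sim_predicted = as.character(pred_sim)
  ), class = "svm_eval_report")
}
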