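#' Construct a beta-value matrix with sample metadata
#'
#' A `beta_matrix` holds a probes-by-samples matrix of methylation
#' beta-values (fractions in `[0, 1]`) together with a per-sample metadata
#' table carrying at least the sample id and, optionally, a `batch` and a
#' `group` label (case/control or tissue).
#'
#' @param beta Numeric matrix, probes in rows and samples in columns; both
#'   dimensions must carry unique names.
#' @param sample_meta Optional `data.frame` with a `sample_id` column (one
#'   row per sample) plus any of `batch`, `group`. Joined on sample id and
#'   reordered to match the columns of `beta`.
#' @return An object of class `beta_matrix`: a list with elements `beta`
#'   and `sample_meta`.
#' @examples
#' b <- matrix(runif(6), 3, 2, dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' bm <- beta_matrix(b)
#' dim(bm)
#' @export
beta_matrix <- function(beta, sample_meta = NULL) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop("'beta' must be a numeric matrix")
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("'beta' must have probe row names and sample column names")
  }
  if (anyDuplicated(rownames(beta))) stop("duplicate probe ids in 'beta'")
  if (anyDuplicated(colnames(beta))) stop("duplicate sample ids in 'beta'")
  bad <- which(is.na(beta) | beta < 0 | beta > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value out of [0, 1] at probe '%s', sample '%s' (value %s)",
      rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]],
      format(beta[bad[1, , drop = FALSE]])
    ))
  }
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = colnames(beta), stringsAsFactors = FALSE)
  } else {
    if (!"sample_id" %in% names(sample_meta)) {
      stop("'sample_meta' must contain a 'sample_id' column")
    }
    idx <- match(colnames(beta), sample_meta$sample_id)
    if (anyNA(idx)) {
      stop(
        "sample metadata missing for sample(s): ",
        paste(colnames(beta)[is.na(idx)], collapse = ", ")
      )
    }
    sample_meta <- sample_meta[idx, , drop = FALSE]
    rownames(sample_meta) <- NULL
  }
  structure(list(beta = beta, sample_meta = sample_meta), class = "beta_matrix")
}

#' @export
dim.beta_matrix <- function(x) dim(x$beta)

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf(
    "beta_matrix: %d probes x %d samples\n", nrow(x$beta), ncol(x$beta)
  ))
  extra <- setdiff(names(x$sample_meta), "sample_id")
  if (length(extra)) cat("sample metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' Probe ids of a container
#' @param x A `beta_matrix` or `signal_matrix`.
#' @return Character vector of probe ids.
#' @export
probe_ids <- function(x) {
  if (inherits(x, "beta_matrix")) return(rownames(x$beta))
  if (inherits(x, "signal_matrix")) return(rownames(x$M))
  stop("unsupported type")
}

#' Sample ids of a container
#' @param x A `beta_matrix` or `signal_matrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) {
  if (inherits(x, "beta_matrix")) return(colnames(x$beta))
  if (inherits(x, "signal_matrix")) return(colnames(x$M))
  stop("unsupported type")
}

#' Construct a two-channel signal-intensity matrix
#'
#' Holds methylated (`M`) and unmethylated (`U`) channel intensities and
#' the per-probe, per-sample detection p-value, all sharing shape and
#' dimnames.
#'
#' @param M,U Numeric matrices of channel intensities (probes x samples).
#' @param detection_p Numeric matrix of detection p-values in `[0, 1]`.
#' @return An object of class `signal_matrix`.
#' @export
signal_matrix <- function(M, U, detection_p) {
  mats <- list(M = M, U = U, detection_p = detection_p)
  for (nm in names(mats)) {
    if (!is.matrix(mats[[nm]]) || !is.numeric(mats[[nm]])) {
      stop(sprintf("'%s' must be a numeric matrix", nm))
    }
  }
  if (!identical(dim(M), dim(U)) || !identical(dim(M), dim(detection_p))) {
    stop("'M', 'U' and 'detection_p' must share dimensions")
  }
  if (!identical(dimnames(M), dimnames(U)) ||
      !identical(dimnames(M), dimnames(detection_p))) {
    stop("'M', 'U' and 'detection_p' must share dimnames")
  }
  if ((nrow(M) > 0 && is.null(rownames(M))) ||
      (ncol(M) > 0 && is.null(colnames(M)))) {
    stop("signal matrices must have probe row names and sample column names")
  }
  if (any(is.na(detection_p) | detection_p < 0 | detection_p > 1)) {
    stop("detection p-values must lie in [0, 1]")
  }
  structure(mats, class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf(
    "signal_matrix: %d probes x %d samples (M, U, detection_p)\n",
    nrow(x$M), ncol(x$M)
  ))
  invisible(x)
}

#' Validate a probe manifest
#'
#' A probe manifest is a `data.frame` with one row per array probe:
#' `probe_id`, `chrom`, `pos` (1-based bp), `design_type` (`"I"` or
#' `"II"`), and optional `snp_af` (population allele frequency of a SNP at
#' the probe, `NA` when none), `nonspecific` (multi-mapping flag) and
#' `island_len_bp`. Rows are sorted by `(chrom, pos)`.
#'
#' @param df A `data.frame` with at least `probe_id`, `chrom`, `pos`,
#'   `design_type`.
#' @return The sorted manifest with class `probe_manifest`.
#' @export
probe_manifest <- function(df) {
  mandatory <- c("probe_id", "chrom", "pos", "design_type")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stop("manifest missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$probe_id)) stop("duplicate probe ids in manifest")
  if (any(is.na(df$pos)) || any(df$pos < 1)) stop("probe positions must be >= 1")
  if (!all(df$design_type %in% c("I", "II"))) {
    stop("design_type must be 'I' or 'II' for every probe")
  }
  if (!"snp_af" %in% names(df)) df$snp_af <- NA_real_
  if (!"nonspecific" %in% names(df)) df$nonspecific <- FALSE
  if (!"island_len_bp" %in% names(df)) df$island_len_bp <- NA_integer_
  ok_af <- is.na(df$snp_af) | (df$snp_af >= 0 & df$snp_af <= 1)
  if (!all(ok_af)) stop("snp_af must lie in [0, 1] or be NA")
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("probe_manifest", "data.frame")
  df
}

#' Construct a set of genomic regions with member probes
#'
#' Regions are stored 1-based, closed (`start` is the first member probe's
#' position, `end` the last one's). Regions must not overlap within a set.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors of 1-based closed interval bounds.
#' @param probes List of character vectors: member probe ids per region,
#'   sorted by position.
#' @return A `data.frame` of class `region_set` with a `probes`
#'   list-column.
#' @export
region_set <- function(chrom = character(), start = integer(),
                       end = integer(), probes = NULL) {
  n <- length(chrom)
  if (length(start) != n || length(end) != n) {
    stop("'chrom', 'start' and 'end' must have equal length")
  }
  if (is.null(probes)) probes <- rep(list(character()), n)
  if (length(probes) != n) stop("'probes' must have one element per region")
  if (any(start > end)) stop("region start must be <= end")
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  df$probes <- probes
  # non-overlap within chromosome
  if (n > 1) {
    o <- order(df$chrom, df$start)
    ds <- df[o, , drop = FALSE]
    same <- ds$chrom[-1] == ds$chrom[-n]
    if (any(same & ds$start[-1] <= ds$end[-n])) {
      stop("regions within a set must not overlap")
    }
    df <- ds
    rownames(df) <- NULL
  }
  class(df) <- c("region_set", "data.frame")
  df
}

#' Number of regions in a region set
#' @param x A `region_set`.
#' @return Integer count.
#' @export
n_regions <- function(x) nrow(x)

#' All member probe ids of a region set
#' @param x A `region_set`.
#' @return Character vector (unique, in region order).
#' @export
region_probes <- function(x) {
  p <- unique(unlist(x$probes, use.names = FALSE))
  if (is.null(p)) character() else p
}

#' Construct a tissue reference profile
#'
#' Per-probe minimum, mean and maximum beta-value for a named tissue, as
#' provided by tissue reference methylome compendia. The mean is the
#' anchor used by the simulator (the input-tissue mean when the profile
#' plays the source role, the target-tissue mean otherwise); min and max
#' bound the first-stage draws.
#'
#' @param tissue Tissue name.
#' @param probe_id Character vector of probe ids.
#' @param min_beta,mean_beta,max_beta Numeric vectors in `[0, 1]` with
#'   `min_beta <= mean_beta <= max_beta` probe-wise.
#' @return A `data.frame` of class `reference_profile` with attribute
#'   `tissue`.
#' @export
reference_profile <- function(tissue, probe_id, min_beta, mean_beta, max_beta) {
  n <- length(probe_id)
  stopifnot(length(min_beta) == n, length(mean_beta) == n, length(max_beta) == n)
  vals <- c(min_beta, mean_beta, max_beta)
  if (any(is.na(vals) | vals < 0 | vals > 1)) {
    stop("reference beta values must lie in [0, 1]")
  }
  if (any(min_beta > mean_beta) || any(mean_beta > max_beta)) {
    stop("reference profile requires min_beta <= mean_beta <= max_beta")
  }
  df <- data.frame(probe_id = probe_id, min_beta = min_beta,
                   mean_beta = mean_beta, max_beta = max_beta,
                   stringsAsFactors = FALSE)
  attr(df, "tissue") <- tissue
  class(df) <- c("reference_profile", "data.frame")
  df
}

#' Per-probe dispersion of a source dataset
#'
#' The simulator's inter-sample noise scale sigma is taken from the
#' source data: one standard deviation of beta across source samples per
#' probe.
#'
#' @param x A `beta_matrix`, or a data.frame with `probe_id` and
#'   `sd_beta`.
#' @return A `data.frame` of class `source_stats`.
#' @export
source_stats <- function(x) {
  if (inherits(x, "beta_matrix")) {
    sds <- apply(x$beta, 1, stats::sd)
    df <- data.frame(probe_id = rownames(x$beta), sd_beta = unname(sds),
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(x)
    if (!all(c("probe_id", "sd_beta") %in% names(df))) {
      stop("source stats need 'probe_id' and 'sd_beta'")
    }
  }
  if (any(is.na(df$sd_beta) | df$sd_beta < 0)) stop("sd_beta must be >= 0")
  class(df) <- c("source_stats", "data.frame")
  df
}

#' Confusion-count evaluation report
#'
#' Builds the standard confusion-derived rates from TP/FP/FN (and
#' optionally TN) counts. Undefined ratios (0/0) are reported as `NA`,
#' never silently as 0.
#'
#' @param tp,fp,fn Non-negative integer counts.
#' @param tn Non-negative integer count, or `NA` when no negative universe
#'   exists (region-level evaluation).
#' @return An object of class `eval_report`: a list with the counts and
#'   `sensitivity`, `specificity`, `accuracy`, `precision`, `recall`,
#'   `f1`.
#' @export
eval_report <- function(tp, fp, fn, tn = NA_integer_) {
  counts <- c(tp = tp, fp = fp, fn = fn)
  if (any(is.na(counts)) || any(counts < 0)) stop("tp, fp, fn must be >= 0")
  if (!is.na(tn) && tn < 0) stop("tn must be >= 0 or NA")
  rat <- function(num, den) if (is.na(den) || den == 0) NA_real_ else num / den
  precision <- rat(tp, tp + fp)
  recall <- rat(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || (precision + recall) == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
    tn = as.integer(tn),
    sensitivity = recall,
    specificity = rat(tn, tn + fp),
    accuracy = rat(tp + ifelse(is.na(tn), 0, tn),
                   tp + fp + fn + ifelse(is.na(tn), NA_integer_, tn)),
    precision = precision, recall = recall, f1 = f1
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: TP=%d FP=%d FN=%d TN=%s\n",
              x$tp, x$fp, x$fn, ifelse(is.na(x$tn), "-", x$tn)))
  cat(sprintf("  precision=%s recall=%s F1=%s\n",
              format(x$precision, digits = 4), format(x$recall, digits = 4),
              format(x$f1, digits = 4)))
  invisible(x)
}
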