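#' Per-batch sample counts of the benchmark cohort design
#'
#' The benchmark draws source samples from five independent cohorts
#' (batches). The large design uses 204, 156, 31, 17 and 24 samples
#' (total 432); the small design uses 14, 6, 4, 4 and 4 (total 32).
#'
#' @param size `"small"` or `"large"`.
#' @return Named integer vector of per-batch counts.
#' @export
benchmark_batch_sizes <- function(size = c("small", "large")) {
  size <- match.arg(size)
  counts <- if (size == "large") c(204L, 156L, 31L, 17L, 24L) else c(14L, 6L, 4L, 4L, 4L)
  names(counts) <- paste0("batch", seq_along(counts))
  counts
}

#' The 12-scenario benchmark grid
#'
#' Scenarios cross cohort size (small: 32 samples; large: 432), target
#' tissue difference (large vs. small mean shift) and the co-methylation
#' correlation threshold (0.1, 0.2, 0.4, which controls how many probes
#' are altered).
#'
#' @param thresholds Correlation thresholds of the region-selection step.
#' @return A `data.frame` with one row per scenario: `scenario_id`,
#'   `size`, `target`, `corr_threshold`, `n_samples`.
#' @export
scenario_grid <- function(thresholds = c(0.1, 0.2, 0.4)) {
  g <- expand.grid(size = c("small", "large"),
                   target = c("large_diff", "small_diff"),
                   corr_threshold = thresholds,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$n_samples <- ifelse(g$size == "large", 432L, 32L)
  g$scenario_id <- sprintf("%s_%s_thr%s", g$size, g$target,
                           sub("^0\\.", "", format(g$corr_threshold)))
  g[, c("scenario_id", "size", "target", "corr_threshold", "n_samples")]
}

#' Split samples into cases and controls within each batch
#'
#' Within every batch, `floor(count / 2)` randomly chosen samples become
#' cases; the remainder stay controls.
#'
#' @param sample_meta `data.frame` with `sample_id` and `batch`.
#' @param seed RNG seed for the within-batch draw.
#' @return Character vector of case sample ids.
#' @export
split_cases <- function(sample_meta, seed = 1) {
  counts <- table(sample_meta$batch)
  if (any(counts < 2)) stop("every batch needs at least 2 samples")
  set.seed(seed)
  unlist(lapply(split(sample_meta$sample_id, sample_meta$batch), function(ids) {
    sample(ids, floor(length(ids) / 2))
  }), use.names = FALSE)
}

#' Samples of the largest batch of a dataset
#'
#' Co-methylation discovery is run on a single homogeneous cohort so
#' that probe-specific batch shifts cannot masquerade as (or drown out)
#' biological co-methylation; this helper extracts the most populous
#' batch. Datasets without batch metadata are returned whole.
#'
#' @param beta A [beta_matrix].
#' @return A [beta_matrix] restricted to the largest batch.
#' @export
discovery_subset <- function(beta) {
  stopifnot(inherits(beta, "beta_matrix"))
  batch <- beta$sample_meta$batch
  if (is.null(batch)) return(beta)
  counts <- table(batch)
  keep <- batch == names(counts)[which.max(counts)]
  beta_matrix(beta$beta[, keep, drop = FALSE],
              beta$sample_meta[keep, , drop = FALSE])
}

#' Build the full simulated benchmark
#'
#' For each scenario of [scenario_grid()]: candidate regions are
#' discovered at the scenario's correlation threshold in the largest
#' batch of the matching source dataset (see [discovery_subset()]), half
#' the samples of every batch are simulated into the target tissue (the
#' rest remain source tissue), and a null twin with the identical
#' case/control split but no probe alteration is emitted alongside.
#'
#' @param sources Named list with `small` and `large` [beta_matrix]
#'   source datasets carrying `batch` metadata.
#' @param manifest A [probe_manifest].
#' @param refs Named list with `input` (source-tissue
#'   [reference_profile]) and one target [reference_profile] per level of
#'   the grid's `target` (`large_diff`, `small_diff`).
#' @param cfg A [simulator_config]; its seed is combined with the
#'   scenario index.
#' @param thresholds Correlation thresholds (default `c(0.1, 0.2, 0.4)`).
#' @param seed Base seed for the case/control splits and the simulator.
#' @return A list of class `benchmark_set`: `grid` plus `scenarios`, a
#'   named list of `list(config, sim, null)` entries.
#' @export
build_scenarios <- function(sources, manifest, refs,
                            cfg = simulator_config("S4"),
                            thresholds = c(0.1, 0.2, 0.4), seed = 1) {
  stopifnot(all(c("small", "large") %in% names(sources)),
            "input" %in% names(refs))
  grid <- scenario_grid(thresholds)
  stats <- lapply(sources, source_stats)
  region_cache <- list()
  scenarios <- vector("list", nrow(grid))
  names(scenarios) <- grid$scenario_id
  for (i in seq_len(nrow(grid))) {
    size <- grid$size[i]
    thr <- grid$corr_threshold[i]
    key <- paste(size, thr)
    if (is.null(region_cache[[key]])) {
      region_cache[[key]] <- select_regions(
        discovery_subset(sources[[size]]), manifest,
        region_config(corr_threshold = thr)
      )
    }
    regions <- region_cache[[key]]
    ref_target <- refs[[grid$target[i]]]
    if (is.null(ref_target)) {
      stop("no target reference profile named '", grid$target[i], "'")
    }
    cases <- split_cases(sources[[size]]$sample_meta, seed = seed + i)
    sim_cfg <- cfg
    sim_cfg$seed <- seed + 1000L + i
    sim <- simulate_tissue(sources[[size]], cases, regions, refs$input,
                           ref_target, stats[[size]], sim_cfg)
    null_cfg <- cfg
    null_cfg$seed <- seed + 2000L + i
    null <- simulate_tissue(sources[[size]], cases, region_set(), refs$input,
                            ref_target, stats[[size]], null_cfg)
    scenarios[[i]] <- list(
      config = c(as.list(grid[i, ]), list(seed = sim_cfg$seed,
                                          approach = cfg$approach)),
      sim = sim, null = null
    )
  }
  structure(list(grid = grid, scenarios = scenarios), class = "benchmark_set")
}

#' @export
print.benchmark_set <- function(x, ...) {
  cat(sprintf("benchmark_set: %d scenarios (plus null twins)\n", nrow(x$grid)))
  print(x$grid, row.names = FALSE)
  invisible(x)
}

#' Fixture-backed inputs for the benchmark
#'
#' Generates everything [build_scenarios()] needs from the synthetic-data
#' module: a manifest, small and large multi-batch source datasets with
#' planted co-methylated regions, and reference profiles whose target
#' means are shifted inside the union of candidate probes of both sources
#' at the loosest threshold (so every scenario's truth probes have a
#' shifted target reference).
#'
#' @param seed Base seed.
#' @param n_probes Number of probes.
#' @param delta_large,delta_small Reference mean shift of the
#'   large-difference and small-difference target tissues.
#' @param noise_sd Logit-scale observation noise of the source data.
#' @param base_threshold Threshold used to designate the shifted
#'   reference probes (the loosest of the grid).
#' @param ... Further arguments passed to [fixture_config()].
#' @return A list with `manifest`, `sources`, `refs`, `truth_regions`.
#' @export
build_benchmark_inputs <- function(seed = 1, n_probes = 2000,
                                   delta_large = 0.35, delta_small = 0.12,
                                   noise_sd = 0.35, base_threshold = 0.1,
                                   ...) {
  cfg_small <- fixture_config(n_probes = n_probes,
                              batch_sizes = benchmark_batch_sizes("small"),
                              noise_sd = noise_sd, seed = seed, ...)
  cfg_large <- fixture_config(n_probes = n_probes,
                              batch_sizes = benchmark_batch_sizes("large"),
                              noise_sd = noise_sd, seed = seed + 17L, ...)
  manifest <- make_manifest(cfg_small)
  truth <- make_truth_regions(cfg_small, manifest)
  sources <- list(
    small = make_source_beta(cfg_small, manifest, truth),
    large = make_source_beta(cfg_large, manifest, truth)
  )
  rc <- region_config(corr_threshold = base_threshold)
  cand <- unique(c(
    region_probes(select_regions(discovery_subset(sources$small), manifest, rc)),
    region_probes(select_regions(discovery_subset(sources$large), manifest, rc))
  ))
  refs_large <- make_reference_pair(cfg_small, manifest, cand, delta = delta_large)
  refs_small <- make_reference_pair(cfg_small, manifest, cand, delta = delta_small)
  list(
    manifest = manifest,
    sources = sources,
    refs = list(input = refs_large$source,
                large_diff = refs_large$target,
                small_diff = refs_small$target),
    truth_regions = truth
  )
}
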