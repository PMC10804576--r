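#' Configuration for the synthetic-data generator
#'
#' The generator emulates every external input the pipeline touches: a
#' 450k-style probe manifest, a multi-batch source beta matrix with
#' planted co-methylated regions, two-channel signal intensities with
#' planted QC defects, and a source/target pair of tissue reference
#' profiles. All outputs are fully determined by `seed`.
#'
#' @param n_probes Number of probes.
#' @param n_chroms Number of chromosomes (probes split evenly; at most 9
#'   so lexicographic chromosome order equals numeric order).
#' @param mean_gap_bp Mean inter-probe gap; gaps are exponential, so a
#'   realistic share exceed the 702 bp region-splitting threshold.
#' @param batch_sizes Integer vector of per-batch sample counts.
#' @param batch_sd SD (logit scale) of the probe-specific batch offsets
#'   drawn when `batch_offsets` is `NULL`; batch effects on arrays are
#'   probe-specific location shifts, so each (probe, batch) pair gets its
#'   own offset.
#' @param batch_offsets Optional explicit per-batch additive offsets on
#'   the logit-beta scale, applied uniformly to all probes (useful for
#'   switching batch effects off with zeros).
#' @param baseline_shapes Two shape parameters of the Beta distribution
#'   generating per-probe baseline means (the default is mildly bimodal,
#'   like array methylation).
#' @param noise_sd Per-observation noise SD on the logit scale.
#' @param comethylation Weight in `[0, 1)` of the shared per-region,
#'   per-sample latent factor; adjacent probes inside a region correlate
#'   at roughly its square on the logit scale.
#' @param delta Mean absolute beta shift between source and target
#'   reference means inside designated regions.
#' @param ref_halfwidth Half-width of the min/max bracket around the
#'   reference mean.
#' @param snp_fraction Fraction of probes flagged with a SNP of allele
#'   frequency > 5%.
#' @param nonspecific_fraction Fraction of probes flagged non-specific.
#' @param n_regions Number of planted co-methylated regions.
#' @param probes_per_region Consecutive probes per planted region.
#' @param signal_total Total (M + U) intensity per probe in signal
#'   fixtures.
#' @param bad_detection_probes,bad_negative_probes,bad_samples Numbers of
#'   planted QC defects in signal fixtures.
#' @param seed RNG seed.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_probes = 2000, n_chroms = 2, mean_gap_bp = 500,
                           batch_sizes = c(14, 6, 4, 4, 4),
                           batch_sd = 0.8, batch_offsets = NULL,
                           baseline_shapes = c(0.85, 0.85),
                           noise_sd = 0.35, comethylation = 0.9,
                           delta = 0.3, ref_halfwidth = 0.05,
                           snp_fraction = 0.05, nonspecific_fraction = 0.02,
                           n_regions = 20, probes_per_region = 5,
                           signal_total = 4000,
                           bad_detection_probes = 0, bad_negative_probes = 0,
                           bad_samples = 0, seed = 1) {
  stopifnot(
    n_probes >= 1, n_chroms >= 1, n_chroms <= 9, mean_gap_bp > 0,
    all(batch_sizes >= 1), batch_sd >= 0, noise_sd >= 0,
    comethylation >= 0, comethylation < 1,
    delta >= 0, delta <= 1, ref_halfwidth > 0, ref_halfwidth < 0.5,
    snp_fraction >= 0, snp_fraction <= 1,
    nonspecific_fraction >= 0, nonspecific_fraction <= 1,
    n_regions >= 0, probes_per_region >= 2, signal_total > 0
  )
  if (!is.null(batch_offsets) && length(batch_offsets) != length(batch_sizes)) {
    stop("'batch_offsets' must match 'batch_sizes' in length")
  }
  structure(as.list(environment()), class = "fixture_config")
}

# Per-probe baseline means, shared between the source-data and the
# reference-profile generators so references anchor the same methylome.
fixture_baselines <- function(cfg) {
  withr_seed(cfg$seed + 104729L, {
    m <- stats::rbeta(cfg$n_probes, cfg$baseline_shapes[1], cfg$baseline_shapes[2])
  })
  pmin(pmax(m, 0.03), 0.95)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate a synthetic probe manifest
#'
#' Probes are laid out per chromosome with exponential inter-probe gaps
#' (mean `cfg$mean_gap_bp`), mixed design types (roughly the 450k I/II
#' proportion), and exactly `round(snp_fraction * n)` SNP-flagged and
#' `round(nonspecific_fraction * n)` non-specific probes.
#'
#' @param cfg A [fixture_config].
#' @return A [probe_manifest].
#' @export
make_manifest <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  n <- cfg$n_probes
  withr_seed(cfg$seed, {
    per_chrom <- diff(round(seq(0, n, length.out = cfg$n_chroms + 1)))
    chrom <- rep(paste0("chr", seq_len(cfg$n_chroms)), per_chrom)
    pos <- unlist(lapply(per_chrom, function(k) {
      gaps <- pmax(2L, as.integer(round(stats::rexp(k, rate = 1 / cfg$mean_gap_bp))))
      1000L + cumsum(gaps)
    }), use.names = FALSE)
    design <- sample(c("I", "II"), n, replace = TRUE, prob = c(0.28, 0.72))
    snp_af <- rep(NA_real_, n)
    n_snp <- round(cfg$snp_fraction * n)
    if (n_snp > 0) {
      snp_idx <- sample.int(n, n_snp)
      snp_af[snp_idx] <- stats::runif(n_snp, 0.06, 0.5)
    }
    nonspecific <- rep(FALSE, n)
    n_ns <- round(cfg$nonspecific_fraction * n)
    if (n_ns > 0) nonspecific[sample.int(n, n_ns)] <- TRUE
    island <- ifelse(stats::runif(n) < 0.3,
                     as.integer(round(stats::runif(n, 12, 2000))), NA_integer_)
  })
  probe_manifest(data.frame(
    probe_id = sprintf("cg%07d", seq_len(n)),
    chrom = chrom, pos = pos, design_type = design,
    snp_af = snp_af, nonspecific = nonspecific, island_len_bp = island,
    stringsAsFactors = FALSE
  ))
}

#' Plant ground-truth co-methylated regions on a manifest
#'
#' Deterministically selects non-overlapping runs of consecutive probes
#' whose internal gaps stay within `max_gap_bp`, whose span is at least
#' `min_len_bp`, and which keep more than `max_gap_bp` of clearance from
#' the previous region so that planted regions never merge during
#' detection.
#'
#' @param cfg A [fixture_config].
#' @param manifest A [probe_manifest].
#' @param max_gap_bp Maximum internal adjacent-probe gap.
#' @param min_len_bp Minimum region span.
#' @return A [region_set] with up to `cfg$n_regions` regions.
#' @export
make_truth_regions <- function(cfg, manifest, max_gap_bp = 702, min_len_bp = 12) {
  k <- cfg$probes_per_region
  sel <- list()
  last_chrom <- ""
  last_end <- -Inf
  i <- 1
  nman <- nrow(manifest)
  # deterministic stride so regions spread over the manifest
  stride <- max(1L, floor(nman / max(1L, cfg$n_regions * (k + 2L))))
  while (i + k - 1 <= nman && length(sel) < cfg$n_regions) {
    idx <- i:(i + k - 1)
    ok <- length(unique(manifest$chrom[idx])) == 1 &&
      all(diff(manifest$pos[idx]) <= max_gap_bp) &&
      (manifest$pos[idx[k]] - manifest$pos[idx[1]] + 1) >= min_len_bp &&
      (manifest$chrom[idx[1]] != last_chrom ||
         manifest$pos[idx[1]] - last_end > max_gap_bp)
    if (ok) {
      sel[[length(sel) + 1]] <- idx
      last_chrom <- manifest$chrom[idx[1]]
      last_end <- manifest$pos[idx[k]]
      i <- i + k + stride
    } else {
      i <- i + 1
    }
  }
  region_set(
    chrom = vapply(sel, function(ix) manifest$chrom[ix[1]], character(1)),
    start = vapply(sel, function(ix) manifest$pos[ix[1]], integer(1)),
    end = vapply(sel, function(ix) manifest$pos[ix[length(ix)]], integer(1)),
    probes = lapply(sel, function(ix) manifest$probe_id[ix])
  )
}

#' Generate a source/target pair of tissue reference profiles
#'
#' Both profiles share the fixture's per-probe baseline methylome. The
#' target mean is shifted by `delta` inside the designated regions (and
#' identical outside); min/max bracket each mean at
#' `cfg$ref_halfwidth`.
#'
#' @param cfg A [fixture_config].
#' @param manifest A [probe_manifest].
#' @param regions A [region_set] (or plain character vector of probe ids)
#'   designating the shifted probes.
#' @param delta Mean shift; defaults to `cfg$delta`.
#' @param direction `"auto"` shifts each region away from its nearer beta
#'   boundary, `"+"`/`"-"` force the sign, `"alternate"` alternates by
#'   region.
#' @return A list with elements `source` and `target`, both
#'   [reference_profile]s.
#' @export
make_reference_pair <- function(cfg, manifest, regions, delta = cfg$delta,
                                direction = c("auto", "+", "-", "alternate")) {
  direction <- match.arg(direction)
  m <- fixture_baselines(cfg)
  names(m) <- manifest$probe_id
  h <- cfg$ref_halfwidth
  if (inherits(regions, "region_set")) {
    plist <- regions$probes
  } else {
    plist <- list(as.character(regions))
  }
  missing <- setdiff(unlist(plist, use.names = FALSE), manifest$probe_id)
  if (length(missing)) {
    stop("region probe(s) not in manifest: ", paste(utils::head(missing, 3), collapse = ", "))
  }
  target_mean <- m
  for (r in seq_along(plist)) {
    p <- plist[[r]]
    s <- switch(direction,
      "auto" = if (mean(m[p]) <= 0.5) 1 else -1,
      "+" = 1, "-" = -1,
      "alternate" = if (r %% 2 == 1) 1 else -1
    )
    target_mean[p] <- pmin(pmax(m[p] + s * delta, 0.001), 0.999)
  }
  mk <- function(tissue, mu) {
    reference_profile(tissue, manifest$probe_id,
                      min_beta = pmax(0, mu - h),
                      mean_beta = mu,
                      max_beta = pmin(1, mu + h))
  }
  list(source = mk("source_tissue", unname(m)),
       target = mk("target_tissue", unname(target_mean)))
}

#' Generate a multi-batch source beta matrix with co-methylated regions
#'
#' Beta values are built on the logit scale as baseline + per-batch
#' offset + noise; probes inside planted regions additionally share a
#' per-region, per-sample latent factor weighted by
#' `cfg$comethylation`, which produces the windowed-correlation signal
#' region discovery expects. Batch offsets are additive on the logit
#' scale (mimicking multiplicative intensity bias) so back-transformed
#' values stay inside (0, 1).
#'
#' @param cfg A [fixture_config].
#' @param manifest A [probe_manifest].
#' @param regions Optional [region_set] of planted co-methylated regions.
#' @return A [beta_matrix] whose `sample_meta` carries the `batch` label.
#' @export
make_source_beta <- function(cfg, manifest, regions = NULL) {
  stopifnot(inherits(cfg, "fixture_config"), inherits(manifest, "probe_manifest"))
  n_samp <- sum(cfg$batch_sizes)
  n_batch <- length(cfg$batch_sizes)
  batch <- rep(paste0("batch", seq_len(n_batch)), cfg$batch_sizes)
  m <- fixture_baselines(cfg)
  lm <- stats::qlogis(m)
  rho <- cfg$comethylation
  withr_seed(cfg$seed + 7919L, {
    offs <- if (is.null(cfg$batch_offsets)) {
      matrix(stats::rnorm(cfg$n_probes * n_batch, 0, cfg$batch_sd),
             cfg$n_probes, n_batch)
    } else {
      matrix(cfg$batch_offsets, cfg$n_probes, n_batch, byrow = TRUE)
    }
    eps <- matrix(stats::rnorm(cfg$n_probes * n_samp), cfg$n_probes, n_samp)
    lb <- lm + offs[, rep(seq_len(n_batch), cfg$batch_sizes), drop = FALSE]
    if (!is.null(regions) && nrow(regions) > 0) {
      z <- matrix(stats::rnorm(nrow(regions) * n_samp), nrow(regions), n_samp)
      for (r in seq_len(nrow(regions))) {
        idx <- match(regions$probes[[r]], manifest$probe_id)
        eps[idx, ] <- rho * matrix(z[r, ], length(idx), n_samp, byrow = TRUE) +
          sqrt(1 - rho^2) * eps[idx, ]
      }
    }
    lb <- lb + cfg$noise_sd * eps
  })
  beta <- pmin(pmax(stats::plogis(lb), 1e-6), 1 - 1e-6)
  dimnames(beta) <- list(manifest$probe_id, sprintf("S%03d", seq_len(n_samp)))
  beta_matrix(beta, data.frame(sample_id = colnames(beta), batch = batch,
                               stringsAsFactors = FALSE))
}

#' Generate two-channel signal intensities with planted QC defects
#'
#' Intensities are consistent with a planted beta matrix through
#' `beta = M / (M + U + offset)` at a fixed total intensity. Defects are
#' planted on request: probes with a failed detection p-value, probes
#' with a negative intensity, and whole samples with depressed medians in
#' both channels (failing the log2-median rule).
#'
#' @param cfg A [fixture_config]; `bad_detection_probes`,
#'   `bad_negative_probes` and `bad_samples` control the planted defects.
#' @param manifest A [probe_manifest].
#' @param beta_offset Intensity offset of the beta formula (default 100).
#' @return A list with `signals` (a [signal_matrix]) and `truth`, which
#'   records the planted beta matrix and the ids of every planted defect.
#' @export
make_signal_matrix <- function(cfg, manifest, beta_offset = 100) {
  stopifnot(inherits(cfg, "fixture_config"))
  n_samp <- sum(cfg$batch_sizes)
  m <- fixture_baselines(cfg)
  withr_seed(cfg$seed + 60013L, {
    lb <- stats::qlogis(m) +
      cfg$noise_sd * matrix(stats::rnorm(cfg$n_probes * n_samp), cfg$n_probes, n_samp)
    beta <- pmin(pmax(stats::plogis(lb), 0.01),
                 cfg$signal_total / (cfg$signal_total + beta_offset) - 0.01)
    detp <- matrix(stats::runif(cfg$n_probes * n_samp, 0, 0.01),
                   cfg$n_probes, n_samp)
    n_defect <- cfg$bad_detection_probes + cfg$bad_negative_probes
    defect_idx <- if (n_defect > 0) sample.int(cfg$n_probes, n_defect) else integer()
    bad_samp_idx <- if (cfg$bad_samples > 0) {
      sample.int(n_samp, cfg$bad_samples)
    } else {
      integer()
    }
  })
  total <- cfg$signal_total + beta_offset
  M <- beta * total
  U <- cfg$signal_total - M
  det_idx <- utils::head(defect_idx, cfg$bad_detection_probes)
  neg_idx <- utils::tail(defect_idx, cfg$bad_negative_probes)
  if (length(det_idx)) detp[det_idx, 1] <- 0.5
  if (length(neg_idx)) M[neg_idx, 1] <- -3
  if (length(bad_samp_idx)) {
    M[, bad_samp_idx] <- M[, bad_samp_idx] * 0.2
    U[, bad_samp_idx] <- U[, bad_samp_idx] * 0.2
  }
  ids <- list(manifest$probe_id, sprintf("S%03d", seq_len(n_samp)))
  dimnames(M) <- dimnames(U) <- dimnames(detp) <- dimnames(beta) <- ids
  list(
    signals = signal_matrix(M, U, detp),
    truth = list(
      beta = beta,
      bad_detection = manifest$probe_id[det_idx],
      bad_negative = manifest$probe_id[neg_idx],
      bad_samples = ids[[2]][bad_samp_idx]
    )
  )
}

#' Materialize a complete fixture bundle on disk
#'
#' Writes manifest.csv, source_beta.tsv, samples.tsv, signals (M/U/
#' detection TSVs), reference_source.csv, reference_target.csv,
#' truth_regions.bed and truth_meta.json into `outdir`.
#'
#' @param cfg A [fixture_config].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_fixture_bundle <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- make_manifest(cfg)
  regions <- make_truth_regions(cfg, manifest)
  src <- make_source_beta(cfg, manifest, regions)
  refs <- make_reference_pair(cfg, manifest, regions)
  sig <- make_signal_matrix(cfg, manifest)
  p <- function(...) file.path(outdir, ...)
  write_manifest(manifest, p("manifest.csv"))
  write_beta_matrix(src, p("source_beta.tsv"), meta_path = p("samples.tsv"))
  write_regions_bed(regions, p("truth_regions.bed"))
  for (nm in c("source", "target")) {
    utils::write.table(as.data.frame(refs[[nm]]),
                       p(sprintf("reference_%s.csv", nm)),
                       sep = ",", quote = FALSE, row.names = FALSE)
  }
  wr <- function(mat, path) {
    utils::write.table(
      data.frame(probe_id = rownames(mat), mat, check.names = FALSE),
      path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  wr(sig$signals$M, p("signals_M.tsv"))
  wr(sig$signals$U, p("signals_U.tsv"))
  wr(sig$signals$detection_p, p("signals_detection_p.tsv"))
  jsonlite::write_json(
    list(seed = cfg$seed, n_probes = cfg$n_probes,
         batch_sizes = cfg$batch_sizes,
         bad_detection = sig$truth$bad_detection,
         bad_negative = sig$truth$bad_negative,
         bad_samples = sig$truth$bad_samples),
    p("truth_meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(list(outdir = outdir))
}
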