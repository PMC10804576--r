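test_that("generators are deterministic under a fixed seed", {
  cfg <- fixture_config(n_probes = 200, batch_sizes = c(6, 6), seed = 11,
                        bad_detection_probes = 2, bad_samples = 1)
  man1 <- make_manifest(cfg)
  man2 <- make_manifest(cfg)
  expect_identical(man1, man2)
  tr <- make_truth_regions(cfg, man1)
  expect_identical(make_source_beta(cfg, man1, tr)$beta,
                   make_source_beta(cfg, man1, tr)$beta)
  s1 <- make_signal_matrix(cfg, man1)
  s2 <- make_signal_matrix(cfg, man1)
  expect_identical(s1$signals$M, s2$signals$M)
  expect_identical(s1$truth, s2$truth)
})

test_that("manifest honours flag fractions and gap distribution", {
  cfg <- fixture_config(n_probes = 10000, n_chroms = 1, mean_gap_bp = 500,
                        snp_fraction = 0.2, nonspecific_fraction = 0.05,
                        seed = 2)
  man <- make_manifest(cfg)
  expect_equal(sum(!is.na(man$snp_af)), round(0.2 * 10000))
  expect_true(all(man$snp_af[!is.na(man$snp_af)] > 0.05))
  expect_equal(sum(man$nonspecific), round(0.05 * 10000))
  gaps <- diff(man$pos)
  expect_lt(abs(mean(gaps) - 500) / 500, 0.1)
  expect_gt(sum(gaps > 702), 0)
  expect_false(is.unsorted(man$pos))
})

test_that("reference pair shifts the target mean only inside regions", {
  cfg <- fixture_config(n_probes = 400, seed = 5, delta = 0.3,
                        baseline_shapes = c(5, 5))
  man <- make_manifest(cfg)
  tr <- make_truth_regions(cfg, man)
  refs <- make_reference_pair(cfg, man, tr, direction = "+")
  inside <- match(region_probes(tr), man$probe_id)
  outside <- setdiff(seq_len(nrow(man)), inside)
  d <- refs$target$mean_beta - refs$source$mean_beta
  expect_equal(max(abs(d[outside])), 0)
  # clamping at the beta boundary can trim a few probes below delta
  expect_gt(mean(abs(d[inside])), 0.25)
  for (p in list(refs$source, refs$target)) {
    expect_true(all(p$min_beta <= p$mean_beta))
    expect_true(all(p$mean_beta <= p$max_beta))
  }
  refs0 <- make_reference_pair(cfg, man, tr, delta = 0)
  expect_equal(refs0$target$mean_beta, refs0$source$mean_beta)
  expect_error(make_reference_pair(cfg, man, c("not_a_probe")), "manifest")
})

test_that("planted co-methylation produces high adjacent-probe correlation", {
  cfg <- fixture_config(n_probes = 300, batch_sizes = 100, comethylation = 0.9,
                        seed = 8)
  man <- make_manifest(cfg)
  tr <- make_truth_regions(cfg, man)
  src <- make_source_beta(cfg, man, tr)
  adj_cor <- function(probes) {
    idx <- match(probes, rownames(src$beta))
    mean(vapply(seq_len(length(idx) - 1), function(i) {
      stats::cor(src$beta[idx[i], ], src$beta[idx[i + 1], ])
    }, numeric(1)))
  }
  in_r <- mean(vapply(tr$probes, adj_cor, numeric(1)))
  expect_gt(in_r, 0.5)
})

test_that("zero batch offsets leave no between-batch mean difference", {
  cfg <- fixture_config(n_probes = 300, batch_sizes = c(40, 40),
                        batch_offsets = c(0, 0), seed = 9)
  man <- make_manifest(cfg)
  src <- make_source_beta(cfg, man)
  b <- src$sample_meta$batch
  d <- rowMeans(src$beta[, b == "batch1"]) - rowMeans(src$beta[, b == "batch2"])
  # no systematic offset: mean difference is pure sampling noise
  expect_lt(abs(mean(d)), 0.01)
  expect_lt(stats::median(abs(d)), 0.05)
})

test_that("signal fixtures are consistent with the planted beta", {
  cfg <- fixture_config(n_probes = 150, batch_sizes = c(5, 5), seed = 12)
  man <- make_manifest(cfg)
  sig <- make_signal_matrix(cfg, man, beta_offset = 100)
  beta <- compute_beta(sig$signals, qc_config(beta_offset = 100))
  expect_lt(max(abs(beta$beta - sig$truth$beta)), 1e-12)
})

test_that("fixtures without planted defects pass QC untouched", {
  cfg <- fixture_config(n_probes = 150, batch_sizes = c(5, 5), seed = 13,
                        snp_fraction = 0, nonspecific_fraction = 0)
  man <- make_manifest(cfg)
  sig <- make_signal_matrix(cfg, man)
  pq <- filter_probes(sig$signals, man)
  expect_equal(nrow(pq$removed), 0)
  sq <- filter_samples(pq$signals)
  expect_equal(nrow(sq$removed), 0)
})

test_that("fixture bundle writes all files and round-trips", {
  dir <- withr::local_tempdir()
  cfg <- fixture_config(n_probes = 80, batch_sizes = c(4, 4), seed = 3)
  write_fixture_bundle(cfg, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "manifest.csv", "source_beta.tsv", "samples.tsv", "truth_regions.bed",
    "reference_source.csv", "reference_target.csv", "signals_M.tsv",
    "truth_meta.json"
  )))))
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 80)
  bm <- read_beta_matrix(file.path(dir, "source_beta.tsv"),
                         meta_path = file.path(dir, "samples.tsv"))
  expect_equal(ncol(bm$beta), 8)
})
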