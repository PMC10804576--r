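test_that("quantile normalization maps columns onto the mean-of-sorted reference", {
  x <- matrix(c(0.1, 0.2, 0.3, 0.2, 0.4, 0.6), 3, 2)
  got <- quantile_normalize(tiny_beta(x))
  expect_equal(unname(got$beta),
               matrix(c(0.15, 0.3, 0.45, 0.15, 0.3, 0.45), 3, 2))

  same <- matrix(c(0.3, 0.1, 0.7, 0.1, 0.3, 0.7), 3, 2)
  out <- quantile_normalize(tiny_beta(same))
  expect_equal(unname(out$beta), unname(same))   # equal distributions: no-op
})

test_that("stratified normalization equalizes within-stratum distributions and is idempotent", {
  set.seed(5)
  x <- matrix(runif(200 * 6), 200, 6)
  strata <- rep(c("I", "II"), c(80, 120))
  bm <- tiny_beta(x)
  n1 <- quantile_normalize(bm, strata)
  for (s in c("I", "II")) {
    idx <- strata == s
    sorted <- apply(n1$beta[idx, ], 2, sort)
    expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  }
  n2 <- quantile_normalize(n1, strata)
  expect_equal(n2$beta, n1$beta, tolerance = 1e-12)
  # rank order preserved within each sample and stratum
  for (j in 1:6) {
    expect_identical(order(n1$beta[strata == "I", j]),
                     order(x[strata == "I", j]))
  }
})

test_that("degenerate strata are left unchanged with a warning", {
  x <- matrix(runif(6), 3, 2)
  expect_warning(out <- quantile_normalize(tiny_beta(x), c("a", "a", "b")),
                 "fewer than 2")
  expect_equal(out$beta[3, ], tiny_beta(x)$beta[3, ])
})

test_that("normalization metrics follow their definitions", {
  # two probes with per-probe sds 0.1 and 0.3 -> median 0.2
  s1 <- c(0.4, 0.5, 0.6) ; s1 <- s1 * (0.1 / stats::sd(s1))
  s2 <- c(0.1, 0.4, 0.7) ; s2 <- s2 * (0.3 / stats::sd(s2))
  x <- rbind(s1 + 0.2, s2 + 0.1)
  x <- pmin(pmax(x, 0), 1)
  bm <- tiny_beta(x)
  x <- bm$beta
  ann <- tiny_manifest(pos = c(100, 200), design = c("I", "II"))
  rep <- norm_metrics(bm, ann, idmr_probes = rownames(x), method = "raw")
  expect_equal(rep$median_probe_sd_all, 0.2, tolerance = 1e-10)
  expect_equal(rep$median_probe_sd_type1, 0.1, tolerance = 1e-10)
  expect_equal(rep$median_probe_sd_type2, 0.3, tolerance = 1e-10)
  # dmrse oracle: sd over samples of the iDMR mean, over sqrt(n)
  per_sample <- colMeans(x)
  expect_equal(rep$dmrse, stats::sd(per_sample) / sqrt(3), tolerance = 1e-12)

  const <- tiny_beta(matrix(0.4, 3, 4))
  ann3 <- tiny_manifest(pos = c(1, 50, 90) + 100)
  rep0 <- norm_metrics(const, ann3, rownames(const$beta))
  expect_equal(rep0$median_probe_sd_all, 0)
  expect_equal(rep0$dmrse, 0)
  expect_warning(norm_metrics(const, ann3, character()), "iDMR")
})

test_that("dmrse matches a brute-force two-step computation on fixtures", {
  cfg <- fixture_config(n_probes = 200, batch_sizes = c(8, 8), seed = 51)
  man <- make_manifest(cfg)
  src <- make_source_beta(cfg, man)
  idmr <- man$probe_id[seq(5, 100, by = 5)]
  rep <- norm_metrics(src, man, idmr)
  means <- vapply(seq_len(ncol(src$beta)), function(j) {
    mean(src$beta[idmr, j])
  }, numeric(1))
  expect_equal(rep$dmrse, stats::sd(means) / sqrt(ncol(src$beta)),
               tolerance = 1e-12)
})

test_that("batch correction removes planted offsets but keeps group signal", {
  cfg <- fixture_config(n_probes = 400, batch_sizes = c(20, 20), batch_sd = 0.8,
                        seed = 52, baseline_shapes = c(5, 5))
  man <- make_manifest(cfg)
  src <- make_source_beta(cfg, man)
  # orthogonal group design: half of each batch is "case", with a real shift
  grp <- rep("control", 40)
  grp[c(1:10, 21:30)] <- "case"
  x <- src$beta
  shift_probes <- 1:40
  x[shift_probes, grp == "case"] <- pmin(x[shift_probes, grp == "case"] + 0.2,
                                         1 - 1e-6)
  bm <- beta_matrix(x, data.frame(sample_id = colnames(x),
                                  batch = src$sample_meta$batch, group = grp,
                                  stringsAsFactors = FALSE))
  corrected <- batch_correct(bm)
  b <- bm$sample_meta$batch
  batch_diff <- function(m) {
    mean(abs(rowMeans(m[, b == "batch1"]) - rowMeans(m[, b == "batch2"])))
  }
  expect_gt(1 - batch_diff(corrected$beta) / batch_diff(x), 0.8)
  grp_effect <- function(m) {
    mean(rowMeans(m[shift_probes, grp == "case"]) -
           rowMeans(m[shift_probes, grp == "control"]))
  }
  expect_lt(abs(grp_effect(corrected$beta) - grp_effect(x)) /
              abs(grp_effect(x)), 0.1)
})

test_that("identical batches come back essentially unchanged", {
  cfg <- fixture_config(n_probes = 200, batch_sizes = c(15, 15),
                        batch_offsets = c(0, 0), seed = 53)
  man <- make_manifest(cfg)
  src <- make_source_beta(cfg, man)
  corrected <- batch_correct(src)
  expect_lt(max(abs(corrected$beta - src$beta)), 0.05)
})

test_that("batch correction validates its design", {
  x <- matrix(runif(40), 10, 4)
  expect_error(batch_correct(tiny_beta(x, batch = rep("b1", 4))),
               "2 batches")
  confounded <- tiny_beta(x, groups = c("case", "case", "control", "control"),
                          batch = c("b1", "b1", "b2", "b2"))
  expect_error(batch_correct(confounded), "confounded")
})
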