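test_that("truncated beta sampling matches its analytic limits", {
  set.seed(1)
  x <- truncated_beta_draw(0.4, 0.5, 0, 1, 1e5)
  se <- sqrt(stats::var(x) / length(x))
  expect_lt(abs(mean(x) - 0.4 / 0.9), 3 * se)

  y <- truncated_beta_draw(0.4, 0.5, 0.3, 0.3 + 1e-9, 100)
  expect_true(all(abs(y - 0.3) < 1e-8))

  expect_error(truncated_beta_draw(0.4, 0.5, 0.6, 0.2, 10), "lo < hi")
})

test_that("truncated beta moments match quadrature of the truncated density", {
  set.seed(2)
  x <- truncated_beta_draw(0.4, 0.5, 0.2, 0.6, 1e5)
  mom <- oracle_trunc_beta_moments(0.4, 0.5, 0.2, 0.6)
  expect_true(all(x >= 0.2 & x <= 0.6))
  expect_lt(abs(mean(x) - mom$mean), 3 * sqrt(mom$var / length(x)))
})

simple_sim_inputs <- function(beta_val = 0.5, n_probes = 4, n_samples = 6) {
  bm <- tiny_beta(matrix(beta_val, n_probes, n_samples))
  ids <- rownames(bm$beta)
  ann_pos <- seq(100L, by = 50L, length.out = n_probes)
  regions <- region_set("chr1", ann_pos[1], ann_pos[n_probes], list(ids))
  list(bm = bm, regions = regions, ids = ids)
}

test_that("S1 is the deterministic reference-difference shift with clamping", {
  inp <- simple_sim_inputs(beta_val = 0.5)
  ref_in <- flat_reference(inp$ids, 0.8)
  ref_tg <- flat_reference(inp$ids, 0.3)
  st <- flat_stats(inp$ids)
  cases <- c("s01", "s02", "s03")
  sim <- simulate_tissue(inp$bm, cases, inp$regions, ref_in, ref_tg, st,
                         simulator_config("S1", clamp_eps = 1e-6))
  # 0.5 - (0.8 - 0.3) = 0 -> clamped to eps
  expect_true(all(sim$beta$beta[, cases] == 1e-6))
  expect_true(all(sim$beta$beta[, c("s04", "s05", "s06")] == 0.5))

  ident <- simulate_tissue(inp$bm, cases, inp$regions, ref_in, ref_in, st,
                           simulator_config("S1"))
  expect_identical(ident$beta$beta, inp$bm$beta)
})

test_that("all approaches conserve controls and out-of-region probes", {
  cfg <- fixture_config(n_probes = 300, batch_sizes = c(8, 8), seed = 41,
                        baseline_shapes = c(5, 5))
  man <- make_manifest(cfg)
  tr <- make_truth_regions(cfg, man)
  src <- make_source_beta(cfg, man, tr)
  refs <- make_reference_pair(cfg, man, tr)
  st <- flat_stats(man$probe_id, 0.02)
  cases <- split_cases(src$sample_meta, seed = 2)
  controls <- setdiff(colnames(src$beta), cases)
  out_probes <- setdiff(rownames(src$beta), region_probes(tr))
  for (app in c("S1", "S2", "S3", "S4")) {
    sim <- simulate_tissue(src, cases, tr, refs$source, refs$target, st,
                           simulator_config(app, seed = 6))
    expect_identical(sim$beta$beta[, controls], src$beta[, controls])
    expect_identical(sim$beta$beta[out_probes, ], src$beta[out_probes, ])
    expect_setequal(sim$truth_probes, region_probes(tr))
    expect_identical(
      sim$beta$beta,
      simulate_tissue(src, cases, tr, refs$source, refs$target, st,
                      simulator_config(app, seed = 6))$beta$beta
    )
  }
})

test_that("case-control difference recovers the planted reference shift", {
  n <- 40
  set.seed(3)
  x <- matrix(runif(n * 40, 0.35, 0.45), n, 40)
  bm <- tiny_beta(x)
  x <- bm$beta
  ids <- rownames(x)
  regions <- region_set("chr1", 100L, 100L + 50L * (n - 1L),
                        list(ids))
  ref_in <- flat_reference(ids, 0.40)
  ref_tg <- flat_reference(ids, 0.70)
  st <- flat_stats(ids, 0.02)
  cases <- sprintf("s%02d", 1:20)
  controls <- sprintf("s%02d", 21:40)
  for (app in c("S1", "S3", "S4")) {
    sim <- simulate_tissue(bm, cases, regions, ref_in, ref_tg, st,
                           simulator_config(app, seed = 4))
    d <- rowMeans(sim$beta$beta[, cases]) - rowMeans(sim$beta$beta[, controls]) -
      (rowMeans(x[, 1:20]) - rowMeans(x[, 21:40]))
    se <- stats::sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - 0.30), max(3 * se, 0.005))
  }
})

test_that("S1 is the zero-noise limit of S3 in equation mode", {
  inp <- simple_sim_inputs(beta_val = 0.4)
  ref_in <- flat_reference(inp$ids, 0.4)
  ref_tg <- flat_reference(inp$ids, 0.6)
  st <- flat_stats(inp$ids, 0)
  cases <- c("s01", "s02")
  s1 <- simulate_tissue(inp$bm, cases, inp$regions, ref_in, ref_tg, st,
                        simulator_config("S1", seed = 1))
  s3 <- simulate_tissue(inp$bm, cases, inp$regions, ref_in, ref_tg, st,
                        simulator_config("S3", s3_mode = "equation", seed = 1))
  expect_equal(s1$beta$beta, s3$beta$beta, tolerance = 1e-12)
})

test_that("S4 first-stage average matches the truncated-beta mean", {
  ids <- "cg00001"
  x <- matrix(0.5, 1, 10000,
              dimnames = list(ids, sprintf("s%05d", 1:10000)))
  bm <- beta_matrix(x)
  regions <- region_set("chr1", 100L, 120L, list(ids))
  ref_in <- flat_reference(ids, 0.5)
  lo <- 0.2; hi <- 0.6
  ref_tg <- reference_profile("t", ids, lo, (lo + hi) / 2, hi)
  st <- flat_stats(ids, 0)           # sd 0: b_i collapses onto the average
  sim <- simulate_tissue(bm, colnames(x), regions, ref_in, ref_tg, st,
                         simulator_config("S4", seed = 9))
  a_bar <- unname(sim$beta$beta[1, 1])       # beta' = 0.5 - (0.5 - a_bar) = a_bar
  mom <- oracle_trunc_beta_moments(0.4, 0.5, lo, hi)
  expect_lt(abs(a_bar - mom$mean), 3 * sqrt(mom$var / 10000))
})

test_that("simulator validates its inputs", {
  inp <- simple_sim_inputs()
  ref_in <- flat_reference(inp$ids, 0.5)
  ref_tg <- flat_reference(inp$ids, 0.5)
  st <- flat_stats(inp$ids)
  expect_error(
    simulate_tissue(inp$bm, "nope", inp$regions, ref_in, ref_tg, st),
    "case_samples"
  )
  bad_regions <- region_set("chr1", 1L, 10L, list("cgXXXXX"))
  expect_error(
    simulate_tissue(inp$bm, "s01", bad_regions, ref_in, ref_tg, st),
    "missing"
  )
})
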