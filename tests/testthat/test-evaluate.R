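test_that("probe-level confusion counts follow the set definitions", {
  universe <- sprintf("cg%03d", 1:20)
  truth <- universe[1:10]
  r <- dmp_eval(truth, truth, universe)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$f1, 1)
  expect_equal(r$tn, 10L)

  r2 <- dmp_eval(universe[1:10], universe[3:12], universe)
  expect_equal(r2$tp, 8L)
  expect_equal(r2$fp, 2L)
  expect_equal(r2$fn, 2L)
  expect_equal(r2$f1, 0.8)
  expect_error(dmp_eval(truth, "not_in_universe", universe), "universe")
})

test_that("probe-level counts match brute-force set comparison on random draws", {
  set.seed(11)
  universe <- sprintf("cg%04d", 1:1000)
  for (rep in 1:5) {
    truth <- sample(universe, sample.int(300, 1))
    pred <- sample(universe, sample.int(300, 1))
    r <- dmp_eval(truth, pred, universe)
    tp <- sum(pred %in% truth)
    expect_equal(r$tp, tp)
    expect_equal(r$fp, length(pred) - tp)
    expect_equal(r$fn, length(truth) - tp)
    expect_equal(r$tn, 1000L - length(union(truth, pred)))
  }
})

test_that("region scoring handles identity and the exact-20% boundary", {
  truth <- region_set(c("chr1", "chr1"), c(100L, 1000L), c(199L, 1499L))
  r <- dmr_eval(truth, truth)
  expect_equal(r$f1, 1)

  # truth length 100, detected length 250, overlap 50:
  # 50 > 20 -> TP; 50 <= 0.2 * 250 -> the detection is also an FP
  t1 <- region_set("chr1", 100L, 199L)
  d1 <- region_set("chr1", 150L, 399L)
  r1 <- dmr_eval(t1, d1)
  expect_equal(r1$tp, 1L)
  expect_equal(r1$fp, 1L)
  expect_equal(r1$fn, 0L)
  expect_equal(r1$precision, 0.5)
  expect_equal(r1$recall, 1)

  expect_error(
    dmr_eval(region_set("chr1", 1L, 10L), region_set("1", 1L, 10L)),
    "naming"
  )
})

test_that("region scoring equals the exhaustive interval oracle", {
  set.seed(12)
  for (rep in 1:200) {
    truth <- random_region_set(sample(2:8, 1))
    detected <- random_region_set(sample(2:8, 1))
    r <- dmr_eval(truth, detected)
    o <- oracle_dmr_eval(truth, detected)
    expect_equal(r$tp, o$tp)
    expect_equal(r$fp, o$fp)
    expect_equal(r$fn, o$fn)
  }
})

test_that("non-overlapping extra detections leave recall alone, lower precision", {
  truth <- region_set("chr1", 100L, 400L)
  d0 <- region_set("chr1", 100L, 400L)
  d1 <- region_set(c("chr1", "chr1"), c(100L, 10000L), c(400L, 10400L))
  r0 <- dmr_eval(truth, d0)
  r1 <- dmr_eval(truth, d1)
  expect_equal(r1$recall, r0$recall)
  expect_lt(r1$precision, r0$precision)
})

test_that("effect stratification splits regions at the fold-change threshold", {
  x <- matrix(0.3, 8, 8)
  x[1:4, 1:4] <- 0.7          # region 1 shift 0.4
  x[5:8, 1:4] <- 0.4          # region 2 shift 0.1
  bm <- tiny_beta(x, groups = rep(c("case", "control"), each = 4))
  x <- bm$beta
  truth <- region_set(c("chr1", "chr1"), c(100L, 1000L), c(400L, 1400L),
                      probes = list(rownames(x)[1:4], rownames(x)[5:8]))
  parts <- stratify_regions_by_effect(truth, bm)
  expect_equal(n_regions(parts$large), 1)
  expect_equal(n_regions(parts$small), 1)
  expect_equal(parts$large$start, 100L)
  expect_equal(parts$effects, c(0.4, 0.1), tolerance = 1e-12)
  expect_equal(n_regions(parts$large) + n_regions(parts$small), n_regions(truth))
})

test_that("guideline improvement is the percent gain over the pipeline mean", {
  f1 <- c(a = 0.6, b = 0.5, c = 0.4)
  expect_equal(guideline_improvement(f1, "a"), 20)
  expect_equal(guideline_improvement(c(a = 0.5, b = 0.5), "a"), 0)
  set.seed(13)
  for (rep in 1:10) {
    scores <- runif(5)
    names(scores) <- letters[1:5]
    best <- names(scores)[which.max(scores)]
    expect_gte(guideline_improvement(scores, best), 0)
  }
  expect_warning(out <- guideline_improvement(c(a = 0, b = 0), "a"), "undefined")
  expect_true(is.na(out))
})

test_that("PCA dispersion is zero for copies, linear in separation, eigen-consistent", {
  set.seed(14)
  a <- matrix(runif(50 * 6), 50, 6)
  expect_equal(pca_dispersion(a, a), 0, tolerance = 1e-10)

  # two point-mass groups separated along one probe axis: the score is
  # exactly the separation
  a0 <- matrix(0.4, 50, 6)
  mk <- function(delta) { m <- a0; m[1, ] <- m[1, ] + delta; m }
  expect_equal(pca_dispersion(a0, mk(0.4)), 0.4, tolerance = 1e-10)
  expect_equal(pca_dispersion(a0, mk(0.8)), 0.8, tolerance = 1e-10)

  # from-scratch oracle: centered covariance eigendecomposition
  b <- matrix(runif(50 * 5), 50, 5)
  comb <- t(cbind(a, b))
  cc <- scale(comb, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(cc))$vectors[, 1:2]
  sc <- cc %*% ev
  want <- sqrt(sum((colMeans(sc[1:6, ]) - colMeans(sc[7:11, ]))^2))
  expect_equal(pca_dispersion(a, b), want, tolerance = 1e-8)

  expect_error(pca_dispersion(a[, 1:2], b[, 1:2], k = 10), "components")
})

make_tissue_panel <- function(n_probes = 120, per_class = 15, delta = 0.3,
                              sigma = 0.02, seed = 15) {
  set.seed(seed)
  centers <- cbind(runif(n_probes, 0.2, 0.5),
                   0, 0)
  centers[, 2] <- pmin(centers[, 1] + delta, 0.98)
  centers[, 3] <- pmax(centers[, 1] - 0.15, 0.02)
  x <- do.call(cbind, lapply(1:3, function(k) {
    matrix(stats::rnorm(n_probes * per_class, centers[, k], sigma),
           n_probes, per_class)
  }))
  x <- pmin(pmax(x, 0), 1)
  rownames(x) <- sprintf("cg%05d", seq_len(n_probes))
  colnames(x) <- sprintf("s%03d", seq_len(ncol(x)))
  list(x = x, labels = rep(c("monocyte", "cd8", "breast"), each = per_class))
}

test_that("well-separated tissue classes classify perfectly; copies stay in class", {
  panel <- make_tissue_panel()
  sim <- panel$x[, panel$labels == "cd8"][, 1:5]
  rep <- svm_eval(panel$x, panel$labels, sim, k = 10, seed = 3)
  expect_equal(rep$train_accuracy, 1)
  expect_equal(rep$test_accuracy, 1)
  expect_true(all(rep$sim_predicted == "cd8"))
  expect_gt(rep$mean_abs_decision, 0)
})

test_that("permuted labels drop CV accuracy to chance", {
  panel <- make_tissue_panel(per_class = 20)
  set.seed(16)
  shuffled <- sample(panel$labels)
  rep <- svm_eval(panel$x, shuffled, panel$x[, 1:3], k = 10, seed = 4)
  expect_lt(rep$train_accuracy, 1 / 3 + 0.25)

  expect_error(svm_eval(panel$x, rep(c("a", "b"), 30), panel$x[, 1:2]),
               "3 classes")
  expect_error(svm_eval(panel$x, rep(c("a", "b", "c"), c(5, 27, 28)),
                        panel$x[, 1:2]),
               "folds")
})
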