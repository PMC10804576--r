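# Independent brute-force oracles used to cross-check the implementation.

# Windowed co-methylation scores by direct cor() calls, probe by probe.
oracle_comethylation <- function(x, ann, window = 3) {
  half <- (window - 1) / 2
  scores <- numeric(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    nb <- which(ann$chrom == ann$chrom[i] &
                  abs(seq_len(nrow(ann)) - i) <= half &
                  seq_len(nrow(ann)) != i)
    if (!length(nb)) next
    cors <- vapply(nb, function(j) {
      if (stats::sd(x[i, ]) == 0 || stats::sd(x[j, ]) == 0) return(0)
      stats::cor(x[i, ], x[j, ])
    }, numeric(1))
    scores[i] <- mean(cors)
  }
  names(scores) <- ann$probe_id
  scores
}

# Candidate regions by an explicit scan over probes.
oracle_candidate_regions <- function(scores, ann, threshold,
                                     max_gap = 702, min_len = 12) {
  out <- list()
  run <- integer()
  flush <- function(run) {
    if (length(run) == 0) return(NULL)
    span <- ann$pos[run[length(run)]] - ann$pos[run[1]] + 1
    if (span < min_len) return(NULL)
    list(chrom = ann$chrom[run[1]], start = ann$pos[run[1]],
         end = ann$pos[run[length(run)]], probes = ann$probe_id[run])
  }
  for (i in seq_len(nrow(ann))) {
    extend <- scores[i] > threshold &&
      (length(run) == 0 ||
         (ann$chrom[i] == ann$chrom[run[length(run)]] &&
            i == run[length(run)] + 1 &&
            ann$pos[i] - ann$pos[run[length(run)]] <= max_gap))
    if (extend) {
      run <- c(run, i)
    } else {
      r <- flush(run)
      if (!is.null(r)) out[[length(out) + 1]] <- r
      run <- if (scores[i] > threshold) i else integer()
    }
  }
  r <- flush(run)
  if (!is.null(r)) out[[length(out) + 1]] <- r
  region_set(
    chrom = vapply(out, `[[`, character(1), "chrom"),
    start = vapply(out, function(o) as.integer(o$start), integer(1)),
    end = vapply(out, function(o) as.integer(o$end), integer(1)),
    probes = lapply(out, `[[`, "probes")
  )
}

# 20%-overlap DMR scoring by exhaustive pairwise interval intersection.
oracle_dmr_eval <- function(truth, detected, frac = 0.2) {
  ov <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1) + 1)
  tp <- 0L; fn <- 0L
  for (i in seq_len(nrow(truth))) {
    cov <- 0
    for (j in seq_len(nrow(detected))) {
      if (truth$chrom[i] != detected$chrom[j]) next
      cov <- cov + ov(truth$start[i], truth$end[i],
                      detected$start[j], detected$end[j])
    }
    if (cov > frac * (truth$end[i] - truth$start[i] + 1)) tp <- tp + 1L else fn <- fn + 1L
  }
  fp <- 0L
  for (j in seq_len(nrow(detected))) {
    best <- 0
    for (i in seq_len(nrow(truth))) {
      if (truth$chrom[i] != detected$chrom[j]) next
      best <- max(best, ov(truth$start[i], truth$end[i],
                           detected$start[j], detected$end[j]))
    }
    if (!(best > frac * (detected$end[j] - detected$start[j] + 1))) fp <- fp + 1L
  }
  list(tp = tp, fp = fp, fn = fn)
}

# Moments of Beta(a, b) truncated to [lo, hi] by numerical quadrature.
oracle_trunc_beta_moments <- function(a, b, lo, hi) {
  z <- stats::pbeta(hi, a, b) - stats::pbeta(lo, a, b)
  mom <- function(k) {
    stats::integrate(function(x) x^k * stats::dbeta(x, a, b) / z, lo, hi,
                     rel.tol = 1e-10)$value
  }
  m1 <- mom(1)
  m2 <- mom(2)
  m4 <- mom(4)
  m3 <- mom(3)
  list(mean = m1, var = m2 - m1^2, m2 = m2, m3 = m3, m4 = m4)
}

# Benjamini-Hochberg by the step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Random non-overlapping region set on given chromosomes.
random_region_set <- function(n, chroms = c("chr1", "chr2"),
                              max_len = 500, max_gap = 2000) {
  per <- table(sample(chroms, n, replace = TRUE))
  ch <- character(); st <- integer(); en <- integer()
  for (c in names(per)) {
    k <- per[[c]]
    starts <- cumsum(sample.int(max_gap, k) + c(0, rep(max_len, k - 1)))
    lens <- sample.int(max_len, k)
    ch <- c(ch, rep(c, k))
    st <- c(st, as.integer(starts))
    en <- c(en, as.integer(starts + lens - 1))
  }
  region_set(ch, st, en)
}
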