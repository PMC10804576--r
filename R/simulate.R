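#' Simulator configuration
#'
#' The simulator alters beta-values of probes inside candidate regions so
#' that case samples mimic a target tissue anchored by reference
#' min/mean/max profiles. Four approaches trade off how much within-region
#' and inter-sample variation is injected:
#'
#' * **S1** - deterministic shift by the difference of reference means.
#' * **S2** - two uniform draws in series: a per-probe average of uniform
#'   draws on the target's min/max bracket, then per-sample uniforms
#'   around that average.
#' * **S3** - per-sample normal draws; the mean is either the target
#'   reference mean (`s3_mode = "equation"`) or a per-probe average of
#'   uniform draws (`s3_mode = "text"`); the SD is the source data's
#'   per-probe SD.
#' * **S4** - per-probe truncated `Beta(0.4, 0.5)` draws on the target's
#'   min/max bracket (within-region / between-CpG variation), averaged,
#'   then per-sample normal draws around the average (inter-sample
#'   variation).
#'
#' @param approach One of `"S1"`, `"S2"`, `"S3"`, `"S4"`.
#' @param beta_alpha,beta_beta Shape parameters of the first-stage Beta
#'   distribution (defaults 0.4 and 0.5).
#' @param clamp_eps Simulated betas are clamped to
#'   `[clamp_eps, 1 - clamp_eps]`.
#' @param s3_mode `"equation"` or `"text"` (see above).
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @return A list of class `simulator_config`.
#' @export
simulator_config <- function(approach = c("S4", "S1", "S2", "S3"),
                             beta_alpha = 0.4, beta_beta = 0.5,
                             clamp_eps = 1e-6,
                             s3_mode = c("equation", "text"), seed = NULL) {
  approach <- match.arg(approach)
  s3_mode <- match.arg(s3_mode)
  stopifnot(beta_alpha > 0, beta_beta > 0, clamp_eps > 0, clamp_eps < 0.5)
  structure(list(approach = approach, beta_alpha = beta_alpha,
                 beta_beta = beta_beta, clamp_eps = clamp_eps,
                 s3_mode = s3_mode, seed = seed), class = "simulator_config")
}

#' Draw from a truncated Beta distribution
#'
#' i.i.d. draws from `Beta(alpha, beta)` conditioned on `[lo, hi]`, via
#' the inverse-CDF transform on `[F(lo), F(hi)]`.
#'
#' @param alpha,beta Shape parameters (> 0).
#' @param lo,hi Truncation bounds, `0 <= lo < hi <= 1`.
#' @param count Number of draws.
#' @return Numeric vector of `count` draws in `[lo, hi]`.
#' @examples
#' x <- truncated_beta_draw(0.4, 0.5, 0.2, 0.6, 1000)
#' range(x)
#' @export
truncated_beta_draw <- function(alpha, beta, lo, hi, count) {
  stopifnot(alpha > 0, beta > 0, count >= 0)
  if (!(lo >= 0 && lo < hi && hi <= 1)) {
    stop("truncation bounds require 0 <= lo < hi <= 1")
  }
  plo <- stats::pbeta(lo, alpha, beta)
  phi <- stats::pbeta(hi, alpha, beta)
  if (phi - plo < .Machine$double.eps) {
    return(rep((lo + hi) / 2, count))
  }
  stats::qbeta(stats::runif(count, plo, phi), alpha, beta)
}

#' Simulate a target tissue inside candidate regions
#'
#' For every probe `p` in a region and every case sample `j`, the
#' simulated beta is
#' `beta'[p, j] = beta[p, j] - (mu_in(p) - b[p, j])`, where `mu_in` is
#' the input-tissue reference mean and `b` the approach-specific draw
#' anchored at the target-tissue reference (see [simulator_config()]).
#' Results are clamped to `[clamp_eps, 1 - clamp_eps]`. Control samples
#' and out-of-region probes are returned bit-identical to the input.
#'
#' @param source A [beta_matrix] of source-tissue samples.
#' @param case_samples Character vector of sample ids to turn into cases.
#' @param regions A [region_set] of candidate regions; its member probes
#'   become the ground-truth altered probes.
#' @param ref_input [reference_profile] of the source (input) tissue.
#' @param ref_target [reference_profile] of the target tissue.
#' @param stats A [source_stats] with the per-probe SD of the source
#'   data.
#' @param cfg A [simulator_config].
#' @return A list of class `sim_result` with elements `beta` (a
#'   [beta_matrix] whose `sample_meta$group` is `"case"`/`"control"`),
#'   `truth_probes`, `truth_regions`, `region_effects` (realized mean
#'   absolute per-region shift) and `config`.
#' @export
simulate_tissue <- function(source, case_samples, regions, ref_input,
                            ref_target, stats, cfg = simulator_config()) {
  stopifnot(inherits(source, "beta_matrix"), inherits(regions, "region_set"))
  samp <- colnames(source$beta)
  if (!all(case_samples %in% samp)) {
    stop("case_samples must be a subset of the source samples")
  }
  probes <- region_probes(regions)
  lookup <- function(ref, what) {
    i <- match(probes, ref$probe_id)
    if (anyNA(i)) {
      stop(sprintf("probe(s) missing from %s: %s", what,
                   paste(utils::head(probes[is.na(i)], 3), collapse = ", ")))
    }
    ref[i, , drop = FALSE]
  }
  if (!all(probes %in% rownames(source$beta))) {
    stop("region probe(s) missing from the source beta matrix")
  }
  rin <- lookup(ref_input, "the input reference")
  rtg <- lookup(ref_target, "the target reference")
  sdv <- lookup(stats, "the source stats")$sd_beta
  if (any(rtg$min_beta > rtg$max_beta)) {
    stop("target reference has min_beta > max_beta for a region probe")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- length(case_samples)
  beta <- source$beta
  ci <- match(case_samples, samp)
  eps <- cfg$clamp_eps
  for (k in seq_along(probes)) {
    lo <- rtg$min_beta[k]
    hi <- rtg$max_beta[k]
    b <- switch(cfg$approach,
      S1 = rep(rtg$mean_beta[k], n),
      S2 = {
        a_bar <- mean(stats::runif(n, lo, hi))
        w <- sqrt(3) * sdv[k]
        stats::runif(n, max(0, a_bar - w), min(1, a_bar + w))
      },
      S3 = {
        m <- if (cfg$s3_mode == "equation") {
          rtg$mean_beta[k]
        } else {
          mean(stats::runif(n, lo, hi))
        }
        stats::rnorm(n, m, sdv[k])
      },
      S4 = {
        a <- if (hi - lo < 1e-12) {
          rep(lo, n)
        } else {
          truncated_beta_draw(cfg$beta_alpha, cfg$beta_beta, lo, hi, n)
        }
        stats::rnorm(n, mean(a), sdv[k])
      }
    )
    newv <- beta[probes[k], ci] - (rin$mean_beta[k] - b)
    beta[probes[k], ci] <- pmin(pmax(newv, eps), 1 - eps)
  }
  meta <- source$sample_meta
  meta$group <- ifelse(meta$sample_id %in% case_samples, "case", "control")
  effects <- vapply(seq_len(nrow(regions)), function(r) {
    p <- regions$probes[[r]]
    mean(abs(rowMeans(beta[p, ci, drop = FALSE]) -
               rowMeans(source$beta[p, ci, drop = FALSE])))
  }, numeric(1))
  structure(list(
    beta = beta_matrix(beta, meta),
    truth_probes = probes,
    truth_regions = regions,
    region_effects = effects,
    config = cfg
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "sim_result (%s): %d probes x %d samples, %d truth regions (%d probes)\n",
    x$config$approach, nrow(x$beta$beta), ncol(x$beta$beta),
    nrow(x$truth_regions), length(x$truth_probes)
  ))
  invisible(x)
}
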