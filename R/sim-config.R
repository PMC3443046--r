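# Simulation configuration and the read-length law.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions the package emulates: long reads
#' with per-base insertion/deletion/mismatch rates of 12%/2%/1% distributed
#' uniformly along the read, mean length 700 bases with 5% of reads longer
#' than 2500, mean coverage 70x, and a validation panel carrying 38 true
#' de novo heterozygous sites and 60 artifact sites.
#'
#' @param p_ins,p_del,p_mis Per-base insertion/deletion/mismatch
#'   probabilities, each in `[0, 1)` with `p_ins + p_del + p_mis < 1`.
#' @param mean_len Target mean read length (bases).
#' @param frac_gt_2500 Target fraction of reads longer than 2500 bases.
#' @param depth Mean per-amplicon fold coverage.
#' @param seed Integer random seed governing the whole simulation.
#' @param n_true_sites,n_artifact_sites Number of TRUE_DE_NOVO (planted
#'   heterozygous) and ARTIFACT (truth-VCF-only) sites.
#' @param base_quality Flat reported PHRED quality written on simulated reads.
#' @param late_cycle_start,late_cycle_mismatch_multiplier Optional
#'   position-dependent mismatch inflation: beyond cycle `late_cycle_start`
#'   the mismatch probability is multiplied by
#'   `late_cycle_mismatch_multiplier`. Defaults (`Inf`, 1) keep errors
#'   position-independent, the behaviour the error model asserts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(p_ins = 0.12, p_del = 0.02, p_mis = 0.01,
                       mean_len = 700, frac_gt_2500 = 0.05, depth = 70,
                       seed = 1L, n_true_sites = 38L, n_artifact_sites = 60L,
                       base_quality = 20L, late_cycle_start = Inf,
                       late_cycle_mismatch_multiplier = 1) {
  probs <- c(p_ins = p_ins, p_del = p_del, p_mis = p_mis)
  assert_that(all(probs >= 0 & probs < 1), "error probabilities must lie in [0, 1)")
  assert_that(sum(probs) < 1, "p_ins + p_del + p_mis must be < 1")
  assert_that(depth > 0, "depth must be positive")
  assert_that(p_mis * late_cycle_mismatch_multiplier < 1,
              "late-cycle mismatch probability must stay below 1")
  structure(list(
    p_ins = p_ins, p_del = p_del, p_mis = p_mis, mean_len = mean_len,
    frac_gt_2500 = frac_gt_2500, depth = depth, seed = as.integer(seed),
    n_true_sites = as.integer(n_true_sites),
    n_artifact_sites = as.integer(n_artifact_sites),
    base_quality = as.integer(base_quality),
    late_cycle_start = late_cycle_start,
    late_cycle_mismatch_multiplier = late_cycle_mismatch_multiplier
  ), class = "sim_config")
}

#' Solve the log-normal read-length law from its two constraints
#'
#' The read-length distribution is log-normal with parameters chosen so that
#' the mean equals `mean_len` and the upper tail beyond `threshold` equals
#' `frac_gt`: `exp(mu + sigma^2/2) = mean_len` and
#' `(log(threshold) - mu)/sigma = qnorm(1 - frac_gt)`. Substituting gives a
#' quadratic in `sigma`; the smaller positive root is taken (the wider root
#' places most mass near zero, which is not a read-length distribution).
#'
#' @param mean_len Target mean length.
#' @param frac_gt Target tail fraction beyond `threshold`.
#' @param threshold Tail threshold in bases.
#' @return Named list with `meanlog` and `sdlog`.
#' @export
lognormal_length_params <- function(mean_len, frac_gt, threshold = 2500) {
  assert_that(mean_len > 0 && threshold > 0, "lengths must be positive")
  if (frac_gt <= 0 || frac_gt >= 1) {
    abort("tail fraction must lie strictly in (0, 1): a log-normal tail is never exactly 0")
  }
  z <- qnorm(1 - frac_gt)
  disc <- z^2 - 2 * log(threshold / mean_len)
  if (disc < 0) {
    abort(sprintf("infeasible length constraints: no log-normal has mean %g and P(L > %g) = %g",
                  mean_len, threshold, frac_gt))
  }
  sdlog <- z - sqrt(disc)
  if (sdlog <= 0) {
    abort("infeasible length constraints: solved sigma is not positive")
  }
  list(meanlog = log(threshold) - sdlog * z, sdlog = sdlog)
}

#' Draw read lengths from the configured law
#'
#' Lengths are log-normal draws truncated below at `min_len`; callers
#' additionally truncate to the available template. With `sdlog = 0` every
#' length equals `exp(meanlog)` (degenerate limit).
#'
#' @param n Number of lengths to draw.
#' @param params List with `meanlog`, `sdlog` (see
#'   [lognormal_length_params()]).
#' @param min_len Minimum emitted length.
#' @return Integer vector of lengths.
#' @export
sample_read_length <- function(n, params, min_len = 50L) {
  len <- if (params$sdlog == 0) {
    rep(exp(params$meanlog), n)
  } else {
    stats::rlnorm(n, params$meanlog, params$sdlog)
  }
  pmax(as.integer(round(len)), as.integer(min_len))
}
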