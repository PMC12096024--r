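#' Type-I error of the paired tests over replicate null cohorts
#'
#' Simulates replicate cohorts through the full rubric pipeline (latent
#' truths, two noisy raters, adjudication) with both arms drawn from the
#' same distribution, so the paired differences are symmetric about zero,
#' and records how often each test rejects at `alpha`.
#'
#' @param n_reps Number of replicate cohorts.
#' @param n_pairs Profiles per cohort.
#' @param instrument Rubric instrument used as the metric.
#' @param mean,sd Latent truth distribution (both arms).
#' @param rater_noise_sd,p_disagreement Rater model.
#' @param alpha Nominal level, default 0.05.
#' @param seed Integer seed.
#' @return List with `t_rate`, `wilcoxon_rate`, `alpha`, `n_reps`, and
#'   `envelope99` (exact binomial 99% envelope of the nominal rate).
#' @export
estimate_null_rejection <- function(n_reps = 2000, n_pairs = 50,
                                    instrument = "COMPREHENSIVENESS",
                                    mean = 50, sd = 6, rater_noise_sd = 3,
                                    p_disagreement = 0.05, alpha = 0.05,
                                    seed = 1) {
  set.seed(seed)
  rej_t <- logical(n_reps); rej_w <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    pairs <- simulate_rubric_pairs(n_pairs, instrument, mean, mean, sd, sd,
                                   rater_noise_sd, p_disagreement)
    ps <- paired_sample(instrument, pairs$profile_id,
                        pairs$total_ai, pairs$total_clin)
    rej_t[r] <- paired_t_test(ps)$p_value < alpha
    rej_w[r] <- wilcoxon_signed_rank(ps)$p_value < alpha
  }
  list(t_rate = mean(rej_t), wilcoxon_rate = mean(rej_w),
       alpha = alpha, n_reps = n_reps,
       envelope99 = stats::qbinom(c(0.005, 0.995), n_reps, alpha) / n_reps)
}

#' Power and effect recovery for the accuracy metric
#'
#' Replicates cohorts of planted mention sets with a configured AI-minus-
#' clinician accuracy shift and reports the rejection rate of the paired
#' comparison (AUTO policy) and the mean recovered arm difference.
#'
#' @param n_reps Number of replicate cohorts.
#' @param n_pairs Profiles per cohort.
#' @param delta Configured accuracy shift on the raw weighted-sum scale.
#' @param table Guideline table; generated once from `seed` when `NULL`.
#' @param alpha Nominal level.
#' @param seed Integer seed.
#' @return List with `power`, `mean_recovered_delta`, `delta`, `n_reps`.
#' @export
estimate_power_accuracy <- function(n_reps = 500, n_pairs = 50, delta = 0.5,
                                    table = NULL, alpha = 0.05, seed = 1) {
  if (is.null(table)) {
    table <- generate_guideline_table(12, seed = substream_seed(seed, "table"))
  }
  set.seed(seed)
  rej <- logical(n_reps); dbar <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    pairs <- simulate_accuracy_pairs(table, n_pairs, delta)
    ps <- paired_sample("accuracy", pairs$profile_id,
                        pairs$acc_ai, pairs$acc_clin)
    rej[r] <- compare_paired(ps, "AUTO", alpha)$significant
    dbar[r] <- mean(ps$d)
  }
  list(power = mean(rej), mean_recovered_delta = mean(dbar),
       delta = delta, n_reps = n_reps)
}

#' Recovery of a configured rubric arm shift
#'
#' @param n_reps Number of replicate cohorts.
#' @param n_pairs Profiles per cohort.
#' @param delta Configured truth shift (AI minus clinician) in points.
#' @param instrument Rubric instrument.
#' @param mean_clin,sd Clinician-arm truth distribution.
#' @param rater_noise_sd,p_disagreement Rater model.
#' @param seed Integer seed.
#' @return List with `mean_recovered_delta`, `mc_se` (Monte-Carlo standard
#'   error of that mean), `delta`, `n_reps`.
#' @export
estimate_recovery_rubric <- function(n_reps = 200, n_pairs = 50, delta = 10,
                                     instrument = "PERSONALIZATION",
                                     mean_clin = 40, sd = 6,
                                     rater_noise_sd = 3,
                                     p_disagreement = 0.05, seed = 1) {
  set.seed(seed)
  dbar <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    pairs <- simulate_rubric_pairs(n_pairs, instrument, mean_clin + delta,
                                   mean_clin, sd, sd, rater_noise_sd,
                                   p_disagreement)
    dbar[r] <- mean(pairs$total_ai - pairs$total_clin)
  }
  list(mean_recovered_delta = mean(dbar),
       mc_se = stats::sd(dbar) / sqrt(n_reps), delta = delta,
       n_reps = n_reps)
}
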