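#' Summary tuple for a metric
#'
#' @param values Numeric vector with at least one value.
#' @return List with `mean`, `sd` (sample SD, `NA` for a single value),
#'   `median`, `q1`, `q3` (linear-interpolation quartiles) and `n`.
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values)) {
    stop("need at least one non-missing value", call. = FALSE)
  }
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
       median = q[2L], q1 = q[1L], q3 = q[3L], n = length(values))
}

#' Construct a paired sample for one metric
#'
#' @param metric Metric name.
#' @param profile_id Identifier of each pair (patient profile).
#' @param x_ai,x_clin Metric values in the AI and clinician arms, aligned by
#'   profile; no missing values.
#' @return A `paired_sample` object with per-pair differences
#'   `d = x_ai - x_clin`.
#' @export
paired_sample <- function(metric, profile_id, x_ai, x_clin) {
  if (length(x_ai) != length(x_clin) || length(profile_id) != length(x_ai)) {
    stop("arms must be aligned by profile", call. = FALSE)
  }
  if (anyNA(x_ai) || anyNA(x_clin)) {
    stop("missing values within a pair are not allowed", call. = FALSE)
  }
  structure(list(metric = metric, profile_id = profile_id,
                 x_ai = as.numeric(x_ai), x_clin = as.numeric(x_clin),
                 d = as.numeric(x_ai) - as.numeric(x_clin),
                 n = length(x_ai)),
            class = "paired_sample")
}

test_result <- function(test, statistic, p_value, n_effective, sample,
                        selected_by = NA_character_, alpha = 0.05) {
  structure(list(metric = sample$metric, test = test,
                 statistic = statistic, p_value = p_value,
                 n = sample$n, n_effective = n_effective,
                 significant = p_value < alpha, alpha = alpha,
                 selected_by = selected_by,
                 summary_ai = summarize_values(sample$x_ai),
                 summary_clin = summarize_values(sample$x_clin)),
            class = "paired_comparison")
}

#' Paired t test on the per-profile differences
#'
#' Two-sided one-sample t test of mean(d) = 0 with df = n - 1 (delegates to
#' [stats::t.test()]).
#'
#' @param sample A [paired_sample()] with n >= 2 and non-degenerate
#'   differences.
#' @return A `paired_comparison` result.
#' @export
paired_t_test <- function(sample) {
  d <- sample$d
  if (length(d) < 2L) stop("paired t test needs n >= 2", call. = FALSE)
  if (stats::sd(d) == 0) {
    stop("differences have zero variance; the paired t statistic is ",
         "undefined (consider the Wilcoxon signed-rank test)", call. = FALSE)
  }
  tt <- stats::t.test(d, mu = 0)
  test_result("PAIRED_T", unname(tt$statistic), tt$p.value,
              length(d), sample)
}

#' Wilcoxon signed-rank test with enumeration-exact small-sample p
#'
#' Zero differences are dropped (classic Wilcoxon); |d| are ranked with
#' midranks for ties. For `n_effective <= exact_limit` the two-sided p-value
#' is exact, from the full null distribution of the positive-rank sum over
#' all 2^n sign assignments (computed by convolution, so ties are handled
#' exactly); above the limit a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param sample A [paired_sample()] with at least one nonzero difference.
#' @param exact_limit Largest `n_effective` for the exact p-value, default 12.
#' @return A `paired_comparison` result; `statistic` is V, the sum of ranks
#'   of positive differences.
#' @export
wilcoxon_signed_rank <- function(sample, exact_limit = 12) {
  d <- sample$d[sample$d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero", call. = FALSE)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- wilcoxon_exact_p(r, v)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- v - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  test_result("WILCOXON", v, p, n, sample)
}

# exact two-sided p for the signed-rank statistic given the midranks of |d|.
# Doubled ranks are integers, so the null distribution of 2*V is built by
# convolution over independent fair sign flips.
wilcoxon_exact_p <- function(ranks, v) {
  w <- as.integer(round(2 * ranks))
  total <- sum(w)
  dist <- c(1, rep(0, total))        # dist[k + 1] = #assignments with 2V = k
  for (wi in w) {
    shifted <- c(rep(0, wi), dist[seq_len(total + 1 - wi)])
    dist <- dist + shifted
  }
  dist <- dist / 2^length(w)
  v2 <- as.integer(round(2 * v))
  p_lo <- sum(dist[seq_len(v2 + 1)])             # P(2V <= v2)
  p_hi <- sum(dist[(v2 + 1):(total + 1)])        # P(2V >= v2)
  min(1, 2 * min(p_lo, p_hi))
}

#' Compare the two arms on one metric
#'
#' With `policy = "AUTO"` a Shapiro-Wilk test on the paired differences at
#' `alpha` selects the paired t test (normality not rejected) or the
#' Wilcoxon signed-rank test (rejected). Degenerate differences with zero
#' variance fall through to Wilcoxon, whose zero-handling applies. The
#' reporting style follows the chosen test: mean/SD for the t test,
#' median/IQR for Wilcoxon.
#'
#' @param sample A [paired_sample()].
#' @param policy `"AUTO"` (default), `"FORCE_T"` or `"FORCE_WILCOXON"`.
#' @param alpha Significance level for both the normality screen and the
#'   significance flag, default 0.05.
#' @return A `paired_comparison` result.
#' @export
compare_paired <- function(sample, policy = c("AUTO", "FORCE_T",
                                              "FORCE_WILCOXON"),
                           alpha = 0.05) {
  policy <- match.arg(policy)
  selected_by <- "forced"
  if (policy == "AUTO") {
    d <- sample$d
    if (length(d) < 3L || stats::sd(d) == 0) {
      choice <- "FORCE_WILCOXON"
      selected_by <- "degenerate differences"
    } else {
      sw_p <- stats::shapiro.test(d)$p.value
      choice <- if (sw_p < alpha) "FORCE_WILCOXON" else "FORCE_T"
      selected_by <- sprintf("shapiro_wilk_p=%.4g", sw_p)
    }
  } else choice <- policy
  res <- if (choice == "FORCE_T") paired_t_test(sample) else
    wilcoxon_signed_rank(sample)
  res$selected_by <- selected_by
  res$alpha <- alpha
  res$significant <- res$p_value < alpha
  res
}

#' Format a p-value in report style
#'
#' Three decimals, `"<.001"` below 0.001.
#' @param p Numeric p-value.
#' @return Character.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<.001", sub("^0\\.", ".", sprintf("%.3f", p)))
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired comparison: %s (n = %d)\n", x$metric, x$n))
  style <- if (x$test == "PAIRED_T") {
    sprintf("AI mean %.2f (SD %.2f) vs clinician mean %.2f (SD %.2f)",
            x$summary_ai$mean, x$summary_ai$sd,
            x$summary_clin$mean, x$summary_clin$sd)
  } else {
    sprintf("AI median %.2f (IQR %.2f-%.2f) vs clinician median %.2f (IQR %.2f-%.2f)",
            x$summary_ai$median, x$summary_ai$q1, x$summary_ai$q3,
            x$summary_clin$median, x$summary_clin$q1, x$summary_clin$q3)
  }
  cat("  ", style, "\n", sep = "")
  cat(sprintf("  %s: statistic = %.4g, P = %s%s\n", x$test, x$statistic,
              format_p(x$p_value),
              if (x$significant) " (significant)" else ""))
  invisible(x)
}
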