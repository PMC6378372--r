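#' Tactile and non-tactile contribution weights
#'
#' Under the linear-summation model, the combined bias is the sum of the
#' biases measured with each input in isolation, and the fractional
#' contribution of the tactile input is
#' `alpha_t = dyer_t / (dyer_t + dyer_nt)`, with
#' `alpha_nt = 1 - alpha_t`. A weight of 1 indicates exclusive contribution
#' of that input. Weights are undefined (flagged, `NA`) when the denominator
#' is within `eps` of zero; they are invariant under positive rescaling of
#' both inputs and swap roles when the inputs are swapped.
#'
#' @param dyer_t Median bias with tactile input only (mm).
#' @param dyer_nt Median bias with non-tactile input only (mm).
#' @param eps Denominator tolerance (mm).
#' @return One-row tibble: `alpha_t`, `alpha_nt`, `defined`.
#' @export
#' @examples
#' cue_weights(7.9, 5.7) # alpha_t = 0.58 (2 dp)
cue_weights <- function(dyer_t, dyer_nt, eps = 1e-6) {
  denom <- dyer_t + dyer_nt
  if (!is.finite(denom))
    abort("Non-finite median bias passed to cue_weights().", class = "fc_stat_error")
  if (abs(denom) <= eps) {
    return(tibble::tibble(alpha_t = NA_real_, alpha_nt = NA_real_, defined = FALSE))
  }
  at <- dyer_t / denom
  tibble::tibble(alpha_t = at, alpha_nt = 1 - at, defined = TRUE)
}

#' Distribution of summed single-cue biases
#'
#' Builds the sample of tactile + non-tactile error sums that the
#' linear-summation model predicts for the combined-input experiment. The
#' two single-cue samples come from different subject groups, so no natural
#' trial pairing exists; three policies are provided:
#'
#' * `"subject_rank_pairing"` (default): both samples are sorted and paired
#'   by rank (for unequal sizes, each rank of the shorter sample is matched
#'   to the proportionally located order statistic of the longer); output
#'   size `min(n_t, n_nt)`.
#' * `"random_pairing"`: seeded random one-to-one pairing of
#'   `min(n_t, n_nt)` values drawn without replacement from each sample.
#' * `"all_pairs"`: every cross-pair, output size `n_t * n_nt`.
#'
#' @param errors_t Numeric sample of tactile-only errors (mm).
#' @param errors_nt Numeric sample of non-tactile-only errors (mm).
#' @param policy Pairing policy.
#' @param seed Seed used by `"random_pairing"`.
#' @return Numeric vector of summed errors.
#' @export
summed_bias_distribution <- function(errors_t, errors_nt,
                                     policy = c("subject_rank_pairing",
                                                "random_pairing", "all_pairs"),
                                     seed = 1) {
  policy <- match.arg(policy)
  if (length(errors_t) == 0 || length(errors_nt) == 0)
    abort("Both samples must be non-empty.", class = "fc_stat_error")
  if (policy == "all_pairs") {
    return(as.vector(outer(errors_t, errors_nt, `+`)))
  }
  m <- min(length(errors_t), length(errors_nt))
  if (policy == "subject_rank_pairing") {
    pick <- function(x) {
      sx <- sort(x)
      if (length(sx) == m) return(sx)
      idx <- pmin(length(sx), pmax(1, round((seq_len(m) - 0.5) * length(sx) / m + 0.5)))
      sx[idx]
    }
    return(pick(errors_t) + pick(errors_nt))
  }
  with_seed(seed, {
    a <- errors_t[sample.int(length(errors_t), m)]
    b <- errors_nt[sample.int(length(errors_nt), m)]
    a + b
  })
}

#' Test of the linear-summation prediction
#'
#' Two-sample Wilcoxon rank-sum comparison of the summed single-cue bias
#' distribution against the combined-input errors. A non-significant
#' difference (`p > alpha`) is consistent with linear summation of the two
#' inputs.
#'
#' @param summed_sample Output of [summed_bias_distribution()].
#' @param exp1_errors Combined-input corrected errors (mm).
#' @param alpha Significance level for the consistency call.
#' @return An [fc_test] with extra field
#'   `consistent_with_linear_summation`.
#' @export
test_linear_summation <- function(summed_sample, exp1_errors, alpha = 0.05) {
  if (length(summed_sample) < 6 || length(exp1_errors) < 6)
    abort("Both samples need >= 6 values.", class = "fc_stat_error")
  res <- rank_sum_test(summed_sample, exp1_errors, alternative = "two.sided")
  res$name <- "linear_summation"
  res$consistent_with_linear_summation <- res$p_value > alpha
  res
}

#' Inverse-variance reliability comparison
#'
#' The reliability of an error distribution is the inverse of its sample
#' variance (1/mm^2). Comparing the combined-input reliability with the two
#' single-cue reliabilities classifies the integration regime:
#'
#' * `reject_summation` — the combined estimate is *less* reliable than both
#'   single cues (`r_exp1 < min(r_exp2, r_exp3)`): linear summation is
#'   rejected.
#' * `optimal_summation` — the combined reliability reaches the additive
#'   (maximum-likelihood) bound `r_exp1 >= r_exp2 + r_exp3`.
#' * `suboptimal_linear_summation` — anything in between; summation occurred
#'   but short of the optimal bound.
#'
#' The classification depends only on the three reliabilities and is
#' invariant under adding a constant to any sample.
#'
#' @param errors_exp1,errors_exp2,errors_exp3 Corrected-error samples (mm)
#'   from the combined, tactile-only and non-tactile-only experiments; each
#'   of length >= 6 with nonzero variance.
#' @return One-row tibble of class `fc_reliability`: `r_exp1`, `r_exp2`,
#'   `r_exp3`, `classification`.
#' @export
reliability_analysis <- function(errors_exp1, errors_exp2, errors_exp3) {
  samples <- list(errors_exp1, errors_exp2, errors_exp3)
  if (any(lengths(samples) < 6))
    abort("Each sample needs >= 6 values.", class = "fc_stat_error")
  v <- vapply(samples, var, numeric(1))
  if (any(v == 0))
    abort("Zero-variance sample; reliability undefined.", class = "fc_stat_error")
  r <- 1 / v
  classification <- if (r[1] < min(r[2], r[3])) {
    "reject_summation"
  } else if (r[1] >= r[2] + r[3]) {
    "optimal_summation"
  } else {
    "suboptimal_linear_summation"
  }
  new_fc_tbl(
    tibble::tibble(r_exp1 = r[1], r_exp2 = r[2], r_exp3 = r[3],
                   classification = classification),
    "fc_reliability"
  )
}

#' Full cue decomposition for one force condition
#'
#' Bundles the linear cue-summation analysis of one condition: the three
#' experiment medians, the contribution weights computed from the tactile
#' and non-tactile medians, the summed-bias distribution with a bootstrap
#' 95% CI of its median, the rank-sum summation test against the
#' combined-input errors, and the inverse-variance reliability triple.
#'
#' @param errors Matching-error tibble covering experiments 1-3 with
#'   `corrected_error` set.
#' @param condition Force condition to decompose.
#' @param policy,seed Passed to [summed_bias_distribution()].
#' @param n_boot Bootstrap replicates for the summed-median CI.
#' @param alpha Significance level of the summation test.
#' @return List of class `fc_cues` with elements `condition`, `dyer_t`,
#'   `dyer_nt`, `dyer_comb`, `weights`, `summed_sample`, `summed_median`,
#'   `summed_ci`, `summation_test`, `reliability`.
#' @export
#' @examples
#' errs <- matching_errors(generate_trials(generator_config(seed = 5)))
#' cue_decomposition(errs, "TUP_IDN", n_boot = 200)
cue_decomposition <- function(errors, condition,
                              policy = "subject_rank_pairing", seed = 1,
                              n_boot = 2000, alpha = 0.05) {
  pull_cell <- function(exp) {
    x <- errors$corrected_error[errors$experiment == exp &
                                  errors$condition == condition]
    if (length(x) == 0)
      abort(sprintf("No errors for experiment %d, condition %s.", exp, condition),
            class = "fc_stat_error")
    x
  }
  e1 <- pull_cell(1); e2 <- pull_cell(2); e3 <- pull_cell(3)
  summed <- summed_bias_distribution(e2, e3, policy = policy, seed = seed)
  structure(
    list(
      condition = condition,
      dyer_t = median(e2),
      dyer_nt = median(e3),
      dyer_comb = median(e1),
      weights = cue_weights(median(e2), median(e3)),
      summed_sample = summed,
      summed_median = median(summed),
      summed_ci = boot_median_ci(summed, n_boot = n_boot,
                                 seed = derive_seed(seed, 7)),
      summation_test = test_linear_summation(summed, e1, alpha = alpha),
      reliability = reliability_analysis(e1, e2, e3)
    ),
    class = "fc_cues"
  )
}

#' @export
print.fc_cues <- function(x, ...) {
  cat(sprintf("<fc_cues> condition %s\n", x$condition))
  cat(sprintf("  medians (mm): tactile %.2f, non-tactile %.2f, combined %.2f\n",
              x$dyer_t, x$dyer_nt, x$dyer_comb))
  if (isTRUE(x$weights$defined)) {
    cat(sprintf("  weights: alpha_t = %.2f, alpha_nt = %.2f\n",
                x$weights$alpha_t, x$weights$alpha_nt))
  } else {
    cat("  weights: undefined (summed median within tolerance of zero)\n")
  }
  cat(sprintf("  summed median %.2f mm (95%% CI %.2f, %.2f); rank-sum p = %.3f (%s)\n",
              x$summed_median, x$summed_ci[1], x$summed_ci[2],
              x$summation_test$p_value,
              if (x$summation_test$consistent_with_linear_summation)
                "consistent with linear summation" else "summation rejected"))
  cat(sprintf("  reliability: %s\n", x$reliability$classification))
  invisible(x)
}
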