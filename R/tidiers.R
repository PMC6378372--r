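#' Tidy a nonparametric test result
#'
#' @param x An [fc_test] object.
#' @param ... Unused.
#' @return One-row tibble with `name`, `statistic`, `z`, `p_value`, `n`,
#'   `tails`, `method`, `degenerate`.
#' @exportS3Method generics::tidy
tidy.fc_test <- function(x, ...) {
  tibble::tibble(name = x$name, statistic = x$statistic, z = x$z,
                 p_value = x$p_value, n = x$n, tails = x$tails,
                 method = x$method, degenerate = x$degenerate)
}

#' Glance at a nonparametric test result
#'
#' @param x An [fc_test] object.
#' @param ... Unused.
#' @return One-row tibble with `p_value`, `method` and, when present,
#'   `consistent_with_linear_summation`.
#' @exportS3Method generics::glance
glance.fc_test <- function(x, ...) {
  out <- tibble::tibble(p_value = x$p_value, method = x$method)
  if (!is.null(x$consistent_with_linear_summation))
    out$consistent_with_linear_summation <- x$consistent_with_linear_summation
  out
}

#' Tidy a cue decomposition
#'
#' @param x An `fc_cues` object from [cue_decomposition()].
#' @param ... Unused.
#' @return One-row tibble with the condition medians, weights, summed-bias
#'   median and CI, summation-test z/p and reliability classification.
#' @exportS3Method generics::tidy
tidy.fc_cues <- function(x, ...) {
  tibble::tibble(
    condition = x$condition,
    dyer_t = x$dyer_t, dyer_nt = x$dyer_nt, dyer_comb = x$dyer_comb,
    alpha_t = x$weights$alpha_t, alpha_nt = x$weights$alpha_nt,
    weights_defined = x$weights$defined,
    summed_median = x$summed_median,
    summed_ci_low = x$summed_ci[1], summed_ci_high = x$summed_ci[2],
    summation_z = x$summation_test$z,
    summation_p = x$summation_test$p_value,
    consistent_with_linear_summation =
      x$summation_test$consistent_with_linear_summation,
    r_exp1 = x$reliability$r_exp1, r_exp2 = x$reliability$r_exp2,
    r_exp3 = x$reliability$r_exp3,
    classification = x$reliability$classification
  )
}

#' Glance at a cue decomposition
#'
#' @param x An `fc_cues` object.
#' @param ... Unused.
#' @return One-row tibble: `condition`, `alpha_t`, `summation_p`,
#'   `consistent_with_linear_summation`, `classification`.
#' @exportS3Method generics::glance
glance.fc_cues <- function(x, ...) {
  tibble::tibble(
    condition = x$condition,
    alpha_t = x$weights$alpha_t,
    summation_p = x$summation_test$p_value,
    consistent_with_linear_summation =
      x$summation_test$consistent_with_linear_summation,
    classification = x$reliability$classification
  )
}
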