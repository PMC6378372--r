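#' Quartiles of the Null-condition error distribution
#'
#' First and third quartiles of the pooled (across subjects)
#' baseline-corrected `NULL`-condition errors of one experiment, using the
#' linear-interpolation quantile definition (R type 7) by default. With 50
#' trials per experiment the quartiles are sensitive to the definition, so
#' the type is switchable.
#'
#' @param null_errors Numeric sample of corrected Null errors (>= 4 values).
#' @param type Quantile type passed to [stats::quantile()].
#' @return Named numeric vector `c(q1 = ..., q3 = ...)`.
#' @export
#' @examples
#' null_quartiles(c(-2, -1, 1, 2)) # c(q1 = -1.25, q3 = 1.25)
null_quartiles <- function(null_errors, type = 7) {
  if (length(null_errors) < 4)
    abort("Need >= 4 Null errors for quartiles.", class = "fc_stat_error")
  q <- quantile(null_errors, c(0.25, 0.75), type = type, names = FALSE)
  c(q1 = q[1], q3 = q[2])
}

#' Strength of bias for one experiment x condition cell
#'
#' The strength of bias measures how consistently a force condition pushes
#' the matching error beyond the range of errors seen without any force.
#' For the experiment's pooled Null interquartile bounds `(q1, q3)`:
#'
#' 1. per subject, `p_pos` is the fraction of that subject's condition
#'    trials with error above `q3` and `p_neg` the fraction below `q1`;
#' 2. each subject's own Null-condition exceedance fractions are subtracted
#'    from both (individual-differences correction);
#' 3. the subject values are averaged, and the signed residual is
#'    `p_pos - p_neg`.
#'
#' A residual near zero means opposite errors were about equally likely; a
#' positive (negative) residual means a consistent upward (downward) bias.
#' Pooled-trial variants of the three quantities (fractions over all trials
#' rather than subject averages; identical when repetition counts are
#' equal) are also reported.
#'
#' @param errors Matching-error tibble with `corrected_error` set,
#'   containing the condition's and the `NULL` trials of the experiment.
#' @param experiment Experiment id.
#' @param condition Condition to score.
#' @param quantile_type Passed to [null_quartiles()].
#' @return One-row tibble: `experiment`, `condition`, `q1_null`, `q3_null`,
#'   `p_pos`, `p_neg`, `residual`, `p_pos_pooled`, `p_neg_pooled`,
#'   `residual_pooled`, `n`.
#' @export
bias_strength <- function(errors, experiment, condition, quantile_type = 7) {
  exp_errors <- errors[errors$experiment == experiment, ]
  null_sub <- exp_errors[exp_errors$condition == "NULL", ]
  cond_sub <- exp_errors[exp_errors$condition == condition, ]
  if (nrow(cond_sub) == 0)
    abort(sprintf("No trials for condition %s in experiment %s.", condition, experiment),
          class = "fc_stat_error")
  q <- null_quartiles(null_sub$corrected_error, type = quantile_type)

  exceed <- function(x) c(pos = mean(x > q[["q3"]]), neg = mean(x < q[["q1"]]))
  subjects <- unique(cond_sub$subject_id)
  missing <- setdiff(subjects, unique(null_sub$subject_id))
  if (length(missing) > 0)
    abort(sprintf("Subject %s has condition trials but no NULL trials in experiment %s.",
                  missing[1], experiment), class = "fc_stat_error")
  per_subject <- purrr::map_dfr(subjects, function(s) {
    pc <- exceed(cond_sub$corrected_error[cond_sub$subject_id == s])
    pn <- exceed(null_sub$corrected_error[null_sub$subject_id == s])
    tibble::tibble(p_pos = pc[["pos"]] - pn[["pos"]],
                   p_neg = pc[["neg"]] - pn[["neg"]])
  })
  p_pos <- mean(per_subject$p_pos)
  p_neg <- mean(per_subject$p_neg)

  pooled_c <- exceed(cond_sub$corrected_error)
  pooled_n <- exceed(null_sub$corrected_error)
  p_pos_pooled <- pooled_c[["pos"]] - pooled_n[["pos"]]
  p_neg_pooled <- pooled_c[["neg"]] - pooled_n[["neg"]]

  tibble::tibble(
    experiment = experiment,
    condition = condition,
    q1_null = q[["q1"]],
    q3_null = q[["q3"]],
    p_pos = p_pos,
    p_neg = p_neg,
    residual = p_pos - p_neg,
    p_pos_pooled = p_pos_pooled,
    p_neg_pooled = p_neg_pooled,
    residual_pooled = p_pos_pooled - p_neg_pooled,
    n = nrow(cond_sub)
  )
}

#' Strength of bias for every cell
#'
#' Applies [bias_strength()] to every experiment x condition cell present in
#' `errors` (including `NULL` itself, whose residual is ~0 by
#' construction).
#'
#' @inheritParams bias_strength
#' @return Tibble of class `fc_strength`, one row per cell; see
#'   [autoplot.fc_strength()].
#' @export
#' @examples
#' errs <- matching_errors(generate_trials(generator_config(seed = 11)))
#' strength_of_bias(errs)
strength_of_bias <- function(errors, quantile_type = 7) {
  cells <- errors |>
    dplyr::distinct(.data$experiment, .data$condition) |>
    dplyr::mutate(condition = factor(.data$condition, levels = fc_conditions)) |>
    dplyr::arrange(.data$experiment, .data$condition) |>
    dplyr::mutate(condition = as.character(.data$condition))
  out <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    bias_strength(errors, cells$experiment[i], cells$condition[i],
                  quantile_type = quantile_type)
  })
  new_fc_tbl(out, "fc_strength")
}
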