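#' Per-trial matching errors
#'
#' The matching error (bias) of a trial is the vertical fingertip distance
#' reproduced in the hold phase minus the distance experienced in the sense
#' phase: `raw_error = hold_dy - sense_dy` (mm). Positive errors mean the
#' thumb was reproduced higher, relative to the index fingertip, than it was
#' sensed.
#'
#' @param trials Trial tibble (typically after [check_trials()] /
#'   [qc_filter()]).
#' @return Tibble with `subject_id`, `experiment`, `condition`,
#'   `repetition`, `raw_error` and `corrected_error` (`NA` until
#'   [baseline_correct()] is applied).
#' @export
#' @examples
#' trials <- generate_experiment(generator_config(seed = 3), 1)
#' raw_errors(trials)
raw_errors <- function(trials) {
  need <- c("subject_id", "experiment", "condition", "repetition",
            "sense_dy", "hold_dy")
  missing <- setdiff(need, names(trials))
  if (length(missing) > 0)
    abort(paste0("Trial table is missing columns: ", toString(missing)),
          class = "fc_error_error")
  if (any(is.na(trials$hold_dy)) || any(is.na(trials$sense_dy)))
    abort("Missing hold_dy or sense_dy value.", class = "fc_error_error")
  tibble::tibble(
    subject_id = trials$subject_id,
    experiment = trials$experiment,
    condition = trials$condition,
    repetition = trials$repetition,
    raw_error = trials$hold_dy - trials$sense_dy,
    corrected_error = NA_real_
  )
}

#' Null-condition baseline correction
#'
#' Removes each subject's idiosyncratic constant bias by subtracting, per
#' subject and experiment, the centre (by default the mean) of that
#' subject's `NULL`-condition raw errors from the raw errors of *all*
#' conditions, including `NULL` itself. With the mean centre, the
#' per-subject mean of corrected `NULL` errors is exactly 0, which makes the
#' correction idempotent.
#'
#' @param errors Output of [raw_errors()].
#' @param center `"mean"` (default) or `"median"` of the Null errors.
#' @return `errors` with `corrected_error` and `baseline` filled in.
#' @export
baseline_correct <- function(errors, center = c("mean", "median")) {
  center <- match.arg(center)
  fun <- if (center == "mean") mean else median
  base <- errors |>
    dplyr::filter(.data$condition == "NULL") |>
    dplyr::group_by(.data$subject_id, .data$experiment) |>
    dplyr::summarise(baseline = fun(.data$raw_error), .groups = "drop")
  missing <- errors |>
    dplyr::distinct(.data$subject_id, .data$experiment) |>
    dplyr::anti_join(base, by = c("subject_id", "experiment"))
  if (nrow(missing) > 0)
    abort(sprintf("No NULL-condition trials for subject %s in experiment %s; cannot baseline-correct.",
                  missing$subject_id[1], missing$experiment[1]),
          class = "fc_error_error")
  errors |>
    dplyr::left_join(base, by = c("subject_id", "experiment")) |>
    dplyr::mutate(corrected_error = .data$raw_error - .data$baseline)
}

#' Raw and baseline-corrected matching errors in one step
#'
#' Convenience wrapper: `baseline_correct(raw_errors(trials), center)`.
#'
#' @inheritParams raw_errors
#' @inheritParams baseline_correct
#' @return See [baseline_correct()].
#' @export
matching_errors <- function(trials, center = "mean") {
  baseline_correct(raw_errors(trials), center = center)
}

#' Summarise one experiment x condition cell
#'
#' Computes the cell's corrected-error median, a seeded bootstrap percentile
#' 95% confidence interval of the median, a one-tailed Wilcoxon signed-rank
#' test against zero whose direction follows the sign of the observed median
#' (two-sided at a zero median), and Cohen's `r = |z| / sqrt(n)`.
#'
#' @param errors Matching-error tibble with `corrected_error` set.
#' @param experiment,condition Cell to summarise.
#' @param n_boot Bootstrap replicates (>= 2000 recommended).
#' @param seed Seed for the bootstrap resampling.
#' @param conf_level Confidence level of the interval.
#' @return One-row tibble: `experiment`, `condition`, `n`, `median`,
#'   `ci_low`, `ci_high`, `wilcoxon_z`, `p_value`, `effect_r`, `degenerate`.
#' @export
summarize_condition <- function(errors, experiment, condition,
                                n_boot = 2000, seed = 1, conf_level = 0.95) {
  x <- errors$corrected_error[errors$experiment == experiment &
                                errors$condition == condition]
  if (length(x) < 6)
    abort(sprintf("Need >= 6 corrected errors for experiment %s, condition %s.",
                  experiment, condition), class = "fc_error_error")
  if (any(is.na(x)))
    abort("corrected_error not set; run baseline_correct() first.",
          class = "fc_error_error")
  med <- median(x)
  degenerate <- length(unique(x)) == 1
  if (degenerate) {
    ci <- c(med, med)
  } else {
    ci <- boot_median_ci(x, n_boot = n_boot, seed = seed, conf_level = conf_level)
  }
  alt <- if (med > 0) "greater" else if (med < 0) "less" else "two.sided"
  wt <- wilcoxon_signed_rank(x, mu = 0, alternative = alt)
  tibble::tibble(
    experiment = experiment,
    condition = condition,
    n = length(x),
    median = med,
    ci_low = ci[1],
    ci_high = ci[2],
    wilcoxon_z = wt$z,
    p_value = wt$p_value,
    effect_r = effect_size_r(wt$z, length(x)),
    degenerate = degenerate
  )
}

# Seeded bootstrap percentile CI of the sample median.
boot_median_ci <- function(x, n_boot = 2000, seed = 1, conf_level = 0.95) {
  n <- length(x)
  a <- (1 - conf_level) / 2
  with_seed(seed, {
    draws <- matrix(sample(x, n * n_boot, replace = TRUE), nrow = n_boot)
    meds <- apply(draws, 1, median)
    unname(quantile(meds, c(a, 1 - a), type = 7))
  })
}

#' Summarise all experiment x condition cells
#'
#' Applies [summarize_condition()] to every cell present in `errors`. Each
#' cell's bootstrap uses a seed derived deterministically from `seed` and
#' the cell's identity, so results are independent of row order.
#'
#' @inheritParams summarize_condition
#' @return Tibble of class `fc_summary` with one row per cell, in
#'   experiment x canonical-condition order; see [autoplot.fc_summary()].
#' @export
#' @examples
#' errs <- matching_errors(generate_experiment(generator_config(seed = 3), 1))
#' summarize_conditions(errs, n_boot = 200)
summarize_conditions <- function(errors, n_boot = 2000, seed = 1,
                                 conf_level = 0.95) {
  cells <- errors |>
    dplyr::distinct(.data$experiment, .data$condition) |>
    dplyr::mutate(condition = factor(.data$condition, levels = fc_conditions)) |>
    dplyr::arrange(.data$experiment, .data$condition) |>
    dplyr::mutate(condition = as.character(.data$condition))
  out <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    cell_seed <- derive_seed(seed, 10 * cells$experiment[i] +
                               match(cells$condition[i], fc_conditions))
    summarize_condition(errors, cells$experiment[i], cells$condition[i],
                        n_boot = n_boot, seed = cell_seed,
                        conf_level = conf_level)
  })
  new_fc_tbl(out, "fc_summary")
}
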