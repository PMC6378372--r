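#' Plot condition summaries
#'
#' Point-range plot of the per-condition median matching error with its
#' bootstrap 95% CI, one panel per experiment — the standard view of the
#' force-condition bias pattern.
#'
#' @param object An `fc_summary` tibble from [summarize_conditions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fc_summary <- function(object, ...) {
  df <- dplyr::mutate(object,
                      condition = factor(.data$condition, levels = fc_conditions))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$median)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)) +
    ggplot2::facet_wrap(~experiment, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Force condition", y = "Matching error (mm)",
                  title = "Median matching error with 95% bootstrap CI") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot strength-of-bias residuals
#'
#' Bar chart of the signed residual exceedance probability per force
#' condition, one panel per experiment.
#'
#' @param object An `fc_strength` tibble from [strength_of_bias()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fc_strength <- function(object, ...) {
  df <- dplyr::mutate(object,
                      condition = factor(.data$condition, levels = fc_conditions))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~experiment, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Force condition", y = "Residual exceedance probability",
                  title = "Strength of bias") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a reliability triple
#'
#' Shows the combined-input reliability against the two single-cue
#' reliabilities and the additive (optimal) bound, mirroring the
#' region-based reading of the inverse-variance comparison.
#'
#' @param object An `fc_reliability` row from [reliability_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fc_reliability <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = 1, y = .data$r_exp1)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$r_exp2,
                                     linetype = "tactile only (r_exp2)")) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$r_exp3,
                                     linetype = "non-tactile only (r_exp3)")) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$r_exp2 + .data$r_exp3,
                                     linetype = "additive bound")) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_x_continuous(breaks = NULL) +
    ggplot2::labs(x = NULL, y = "Reliability (1/mm^2)",
                  linetype = NULL,
                  title = paste0("Reliability comparison: ", object$classification)) +
    ggplot2::theme_minimal()
}

#' Plot matching error against repetition
#'
#' Trial-level scatter of matching error over the repetition index (all
#' subjects' first repetitions, then second, and so on), with a linear fit —
#' the visual companion of [fatigue_correlation()].
#'
#' @param errors Matching-error tibble.
#' @param conditions Conditions to show.
#' @return A ggplot object.
#' @export
plot_fatigue <- function(errors, conditions = c("TUP_IDN", "TDN_IUP")) {
  df <- dplyr::filter(errors, .data$condition %in% conditions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$repetition, y = .data$corrected_error)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_grid(condition ~ experiment, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Repetition", y = "Matching error (mm)",
                  title = "Matching error as a function of repetition") +
    ggplot2::theme_minimal()
}
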