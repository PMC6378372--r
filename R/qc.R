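#' Sense-phase compliance limits
#'
#' Windows the protocol imposes during the sense phase: collinear vertical
#' distance within `0 +/- dy_tol` mm, horizontal distance within
#' `dz_nominal +/- dz_tol` mm, normal digit force inside `fn_range` N and
#' tangential force magnitude inside `ft_range_abs` N (with the direction
#' prescribed by the condition). `zero_tol` is the force magnitude below
#' which a digit counts as force-free in the `NULL` and `FN_ONLY`
#' conditions.
#'
#' @param dy_tol,dz_tol Position tolerances (mm), > 0.
#' @param dz_nominal Nominal horizontal distance (mm).
#' @param fn_range Allowed normal-force range (N).
#' @param ft_range_abs Allowed tangential-force magnitude range (N).
#' @param zero_tol Zero-force tolerance (N).
#' @return List of class `fc_limits`.
#' @export
compliance_limits <- function(dy_tol = 3, dz_nominal = 65, dz_tol = 3,
                              fn_range = c(4, 5), ft_range_abs = c(2.5, 3.5),
                              zero_tol = 0.25) {
  if (dy_tol <= 0 || dz_tol <= 0)
    abort("Tolerances must be > 0.", class = "fc_config_error")
  if (fn_range[1] >= fn_range[2] || ft_range_abs[1] >= ft_range_abs[2])
    abort("Force ranges must be increasing.", class = "fc_config_error")
  structure(list(dy_tol = dy_tol, dz_nominal = dz_nominal, dz_tol = dz_tol,
                 fn_range = fn_range, ft_range_abs = ft_range_abs,
                 zero_tol = zero_tol),
            class = "fc_limits")
}

#' Vertical fingertip distance
#'
#' `d_y` is the vertical coordinate of the thumb contact point minus that of
#' the index fingertip: positive values mean the thumb is higher.
#'
#' @param thumb_y,index_y Vertical coordinates (mm); finite, vectorised.
#' @return `thumb_y - index_y` (mm).
#' @export
#' @examples
#' compute_dy(12, 5)
compute_dy <- function(thumb_y, index_y) {
  if (any(!is.finite(thumb_y)) || any(!is.finite(index_y)))
    abort("Non-finite coordinate passed to compute_dy().", class = "fc_stat_error")
  thumb_y - index_y
}

#' Per-trial compliance check
#'
#' Applies the sense-phase windows trial by trial and fills `qc_pass` and a
#' `violations` column (semicolon-separated labels, empty when compliant).
#' A trial passes iff its sense-phase `d_y` and `d_z` are inside their
#' windows and its forces match the condition: both normal forces in range
#' for every non-`NULL` condition, tangential forces inside the magnitude
#' range with the prescribed direction for the four tangential conditions,
#' and forces below `zero_tol` where the condition requires none. The check
#' is a pure per-row predicate: row order never changes any flag.
#'
#' @param trials Trial tibble.
#' @param limits A [compliance_limits()] object.
#' @return `trials` with `qc_pass` (logical) and `violations` (character).
#' @export
check_trials <- function(trials, limits = compliance_limits()) {
  check_trial_columns(trials)
  unknown <- setdiff(unique(trials$condition), fc_conditions)
  if (length(unknown) > 0)
    abort(paste0("Unknown condition label(s): ", toString(unknown)),
          class = "fc_qc_error")

  n <- nrow(trials)
  viol <- vector("list", n)
  add <- function(idx, label) {
    for (i in which(idx)) viol[[i]] <<- c(viol[[i]], label)
  }

  add(abs(trials$sense_dy) > limits$dy_tol, "dy_out_of_window")
  add(abs(trials$sense_dz - limits$dz_nominal) > limits$dz_tol, "dz_out_of_window")

  cond <- trials$condition
  needs_fn <- cond != "NULL"
  for (digit in c("thumb", "index")) {
    fn <- trials[[paste0(digit, "_fn")]]
    add(needs_fn & fn < limits$fn_range[1], sprintf("normal_below_range(%s)", digit))
    add(needs_fn & fn > limits$fn_range[2], sprintf("normal_above_range(%s)", digit))

    s <- purrr::map_dbl(fc_tangential_sign[cond], digit)
    ft <- trials[[paste0(digit, "_ft")]]
    signed <- s * ft # expected to land in ft_range_abs when s != 0
    add(s != 0 & signed < limits$ft_range_abs[1], sprintf("tangential_below_range(%s)", digit))
    add(s != 0 & signed > limits$ft_range_abs[2], sprintf("tangential_above_range(%s)", digit))
  }

  is_null <- cond == "NULL"
  any_force <- abs(trials$thumb_fn) > limits$zero_tol |
    abs(trials$index_fn) > limits$zero_tol |
    abs(trials$thumb_ft) > limits$zero_tol |
    abs(trials$index_ft) > limits$zero_tol
  add(is_null & any_force, "force_in_null")
  any_ft <- abs(trials$thumb_ft) > limits$zero_tol | abs(trials$index_ft) > limits$zero_tol
  add(cond == "FN_ONLY" & any_ft, "tangential_in_fn_only")

  trials$qc_pass <- lengths(viol) == 0
  trials$violations <- purrr::map_chr(viol, function(v) paste(v, collapse = ";"))
  trials
}

#' Drop (or keep) trials failing QC
#'
#' @param trials Output of [check_trials()].
#' @param drop_failed Drop failing trials (default) or keep everything.
#' @param quiet Suppress the log message.
#' @return Filtered tibble.
#' @export
qc_filter <- function(trials, drop_failed = TRUE, quiet = FALSE) {
  if (!"violations" %in% names(trials))
    abort("Run check_trials() before qc_filter().", class = "fc_qc_error")
  n_fail <- sum(!trials$qc_pass)
  if (!drop_failed) return(trials)
  if (!quiet && n_fail > 0)
    inform(sprintf("qc_filter: dropping %d of %d non-compliant trial(s).",
                   n_fail, nrow(trials)))
  dplyr::filter(trials, .data$qc_pass)
}

#' Group-level compliance tests
#'
#' Pooled (across subjects) equivalence-style checks that the sense-phase
#' variables stayed inside their windows, per condition: for each tested
#' variable two one-sided Wilcoxon signed-rank tests are run against the
#' window bounds — one that the values do not exceed the upper bound, one
#' that they do not fall below the lower bound — and the cell passes iff
#' both p-values exceed `alpha`. `sense_dy` is tested against `0 +/- dy_tol`
#' and `sense_dz` against `dz_nominal +/- dz_tol`; normal forces against
#' `fn_range` in every non-`NULL` condition; tangential forces against the
#' signed window implied by the condition's force directions. Cells whose
#' deviations from the bound are all zero are reported as trivially passing
#' (`p = 1`) and flagged degenerate.
#'
#' @param trials Trial tibble (typically before QC filtering).
#' @param limits A [compliance_limits()].
#' @param alpha Significance level for the pass criterion.
#' @return Tibble with one row per condition x variable: `variable`,
#'   `condition`, `statistic` (z of the worse-case side), `p_value` (the
#'   smaller one-sided p), `n`, `passed`, `degenerate`.
#' @export
group_compliance_tests <- function(trials, limits = compliance_limits(),
                                   alpha = 0.05) {
  check_trial_columns(trials)
  cells <- list()
  push <- function(variable, condition, values, lower, upper) {
    cells[[length(cells) + 1]] <<- list(variable = variable, condition = condition,
                                        values = values, lower = lower, upper = upper)
  }
  for (cond in intersect(fc_conditions, unique(trials$condition))) {
    sub <- trials[trials$condition == cond, ]
    push("sense_dy", cond, sub$sense_dy, -limits$dy_tol, limits$dy_tol)
    push("sense_dz", cond, sub$sense_dz,
         limits$dz_nominal - limits$dz_tol, limits$dz_nominal + limits$dz_tol)
    if (cond != "NULL") {
      push("thumb_fn", cond, sub$thumb_fn, limits$fn_range[1], limits$fn_range[2])
      push("index_fn", cond, sub$index_fn, limits$fn_range[1], limits$fn_range[2])
    }
    sgn <- fc_tangential_sign[[cond]]
    for (digit in c("thumb", "index")) {
      if (sgn[[digit]] != 0) {
        rng <- sort(sgn[[digit]] * limits$ft_range_abs)
        push(paste0(digit, "_ft"), cond, sub[[paste0(digit, "_ft")]], rng[1], rng[2])
      }
    }
  }
  purrr::map_dfr(cells, function(cell) {
    if (length(cell$values) < 6)
      abort(sprintf("Fewer than 6 trials for %s in condition %s.",
                    cell$variable, cell$condition), class = "fc_qc_error")
    up <- wilcoxon_signed_rank(cell$values, mu = cell$upper, alternative = "greater")
    lo <- wilcoxon_signed_rank(cell$values, mu = cell$lower, alternative = "less")
    worst <- if (up$p_value <= lo$p_value) up else lo
    tibble::tibble(
      variable = cell$variable,
      condition = cell$condition,
      statistic = worst$z,
      p_value = worst$p_value,
      n = length(cell$values),
      passed = up$p_value > alpha && lo$p_value > alpha,
      degenerate = up$degenerate || lo$degenerate
    )
  })
}
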