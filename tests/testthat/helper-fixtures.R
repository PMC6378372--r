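`%||%` <- function(x, y) if (is.null(x)) y else x

# Build a minimal compliant trial row set by hand; defaults sit well inside
# every compliance window for the given condition.
make_trial <- function(subject_id = "S01", experiment = 1L, condition = "TUP_IDN",
                       repetition = 1L, sense_dy = 0, hold_dy = 0,
                       sense_dz = 65, thumb_fn = 4.5, index_fn = 4.5,
                       thumb_ft = NULL, index_ft = NULL) {
  sgn <- list(TUP_IUP = c(1, 1), TDN_IDN = c(-1, -1), TUP_IDN = c(1, -1),
              TDN_IUP = c(-1, 1), `NULL` = c(0, 0), FN_ONLY = c(0, 0))[[condition]]
  if (condition == "NULL") thumb_fn <- index_fn <- 0
  tibble::tibble(
    subject_id = subject_id, experiment = as.integer(experiment),
    condition = condition, repetition = as.integer(repetition),
    sense_dy = sense_dy, hold_dy = hold_dy, sense_dz = sense_dz,
    thumb_fn = thumb_fn, index_fn = index_fn,
    thumb_ft = thumb_ft %||% (sgn[1] * 3), index_ft = index_ft %||% (sgn[2] * 3),
    qc_pass = NA
  )
}

# Trial table for one subject with given raw errors per condition:
# hold_dy = error, sense_dy = 0.
make_subject_errors <- function(subject_id, experiment, errors_by_condition) {
  purrr::imap_dfr(errors_by_condition, function(errs, cond) {
    purrr::map_dfr(seq_along(errs), function(k) {
      make_trial(subject_id = subject_id, experiment = experiment,
                 condition = cond, repetition = k, hold_dy = errs[k])
    })
  })
}

# Noise-free generator config: every matching error equals its configured
# effect exactly.
quiet_config <- function(...) {
  generator_config(subject_baseline_sd = 0, trial_noise_sd = 0,
                   sense_dy_jitter = 0, dz_jitter = 0, ...)
}

sample_skewness <- function(x) {
  mean((x - mean(x))^3) / stats::sd(x)^3
}
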