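#' Read and write trial tables
#'
#' Trial tables are plain UTF-8 CSV files with a header row and columns in
#' the fixed order `subject_id, experiment, condition, repetition, sense_dy,
#' hold_dy, sense_dz, thumb_fn, index_fn, thumb_ft, index_ft, qc_pass`.
#' Numeric fields round-trip at full double precision. `read_trials()`
#' validates the structure (exact column set, numeric types, no duplicate
#' `(subject, experiment, condition, repetition)` keys); semantic invariants
#' such as "no forces in the NULL condition" are checked separately by
#' [trial_invariants()].
#'
#' @param trials A trial tibble as produced by [generate_experiment()].
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` returns
#'   the validated tibble.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' trials <- generate_experiment(generator_config(seed = 1), 1)
#' write_trials(trials, f)
#' identical(dim(read_trials(f)), dim(trials))
write_trials <- function(trials, path) {
  check_trial_columns(trials)
  readr::write_csv(trials[, fc_trial_cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      experiment = readr::col_integer(),
      condition = readr::col_character(),
      repetition = readr::col_integer(),
      sense_dy = readr::col_double(),
      hold_dy = readr::col_double(),
      sense_dz = readr::col_double(),
      thumb_fn = readr::col_double(),
      index_fn = readr::col_double(),
      thumb_ft = readr::col_double(),
      index_ft = readr::col_double(),
      qc_pass = readr::col_logical()
    ),
    progress = FALSE
  )
  check_trial_columns(trials)
  probs <- readr::problems(trials)
  if (nrow(probs) > 0)
    abort(sprintf("Non-numeric or malformed values in %s (first at row %d).",
                  path, probs$row[1]), class = "fc_io_error")
  dup <- duplicated(trials[, c("subject_id", "experiment", "condition", "repetition")])
  if (any(dup))
    abort(sprintf("Duplicate trial keys in %s (e.g. subject %s, experiment %s, condition %s, repetition %s).",
                  path, trials$subject_id[dup][1], trials$experiment[dup][1],
                  trials$condition[dup][1], trials$repetition[dup][1]),
          class = "fc_io_error")
  trials
}

check_trial_columns <- function(trials) {
  missing <- setdiff(fc_trial_cols, names(trials))
  # `violations` is appended by check_trials() and may legitimately tag along
  extra <- setdiff(names(trials), c(fc_trial_cols, "violations"))
  if (length(missing) > 0)
    abort(paste0("Trial table is missing columns: ", toString(missing)),
          class = "fc_io_error")
  if (length(extra) > 0)
    abort(paste0("Trial table has unexpected columns: ", toString(extra)),
          class = "fc_io_error")
  invisible(trials)
}

#' Check semantic trial-table invariants
#'
#' Flags rows breaching the record-level invariants that structural CSV
#' validation cannot see: nonzero forces in the `NULL` condition, nonzero
#' tangential forces in `FN_ONLY`, unknown condition labels, and repetition
#' indices below 1.
#'
#' @param trials Trial tibble.
#' @param zero_tol Force magnitude (N) below which a force counts as zero.
#' @return Tibble with columns `row`, `subject_id`, `condition`,
#'   `invariant`; zero rows when everything holds.
#' @export
trial_invariants <- function(trials, zero_tol = 0.25) {
  check_trial_columns(trials)
  flag <- function(idx, label) {
    tibble::tibble(row = idx,
                   subject_id = trials$subject_id[idx],
                   condition = trials$condition[idx],
                   invariant = label)
  }
  out <- list()
  unknown <- which(!trials$condition %in% fc_conditions)
  if (length(unknown)) out <- c(out, list(flag(unknown, "unknown_condition")))
  is_null <- trials$condition == "NULL"
  forced <- is_null &
    (abs(trials$thumb_fn) > zero_tol | abs(trials$index_fn) > zero_tol |
       abs(trials$thumb_ft) > zero_tol | abs(trials$index_ft) > zero_tol)
  if (any(forced)) out <- c(out, list(flag(which(forced), "force_in_null")))
  fn_only <- trials$condition == "FN_ONLY" &
    (abs(trials$thumb_ft) > zero_tol | abs(trials$index_ft) > zero_tol)
  if (any(fn_only)) out <- c(out, list(flag(which(fn_only), "tangential_in_fn_only")))
  bad_rep <- which(trials$repetition < 1)
  if (length(bad_rep)) out <- c(out, list(flag(bad_rep, "repetition_below_one")))
  if (length(out) == 0) {
    tibble::tibble(row = integer(), subject_id = character(),
                   condition = character(), invariant = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(out), .data$row)
  }
}

#' Read a generator configuration from YAML
#'
#' Reads a YAML file whose top-level keys match [generator_config()]
#' arguments and merges it over the defaults. `condition_effect` may be given
#' as a nested map `experiment -> condition -> mm`; unspecified cells keep
#' their default.
#'
#' @param path YAML file path.
#' @return A validated `fc_config`.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(generator_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    abort(paste0("Unknown generator config fields: ", toString(unknown)),
          class = "fc_config_error")
  if (!is.null(raw$condition_effect)) {
    m <- default_condition_effects()
    for (exp in names(raw$condition_effect)) {
      for (cond in names(raw$condition_effect[[exp]])) {
        m[exp, cond] <- raw$condition_effect[[exp]][[cond]]
      }
    }
    raw$condition_effect <- m
  }
  if (!is.null(raw$reps_per_condition)) {
    raw$reps_per_condition <- unlist(raw$reps_per_condition)
  }
  if (!is.null(raw$force_limits)) {
    raw$force_limits <- lapply(raw$force_limits, unlist)
  }
  do.call(generator_config, raw)
}
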