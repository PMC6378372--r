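#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> QC -> matching errors -> condition summaries ->
#' cue decomposition -> strength of bias as one reproducible run, writing
#' every stage's output under `out_dir`:
#'
#' * `trials.csv` — generated (or supplied) trial table
#' * `trials_qc.csv` — trials with `qc_pass` / `violations` filled
#' * `qc.json` — group-level compliance test results
#' * `errors.csv` — raw and baseline-corrected matching errors
#' * `summary.json` — per experiment x condition summaries (medians, CIs,
#'   Wilcoxon z/p, effect sizes)
#' * `cues.json` — cue decomposition for the opposite-direction conditions
#' * `strength.json` — strength-of-bias rows for every cell
#' * `manifest.json` — config snapshot, seed, package version, file
#'   checksums and row counts
#'
#' A single `seed` governs every stochastic stage through derived streams,
#' so re-running with the same inputs reproduces all numeric outputs
#' byte-identically (the manifest's timestamp aside).
#'
#' @param config A [generator_config()]; its `seed` is replaced by `seed`.
#' @param seed Master seed for the run.
#' @param out_dir Output directory (created if needed).
#' @param trials Optional pre-existing trial table; when supplied the
#'   simulate stage is skipped and `config` only drives analysis settings.
#' @param experiments Experiments to simulate.
#' @param n_boot Bootstrap replicates for all CIs.
#' @param drop_failed_qc Drop non-compliant trials before analysis.
#' @param policy Pairing policy for [summed_bias_distribution()].
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list of class `fc_run` with all stage outputs and
#'   `out_dir`.
#' @export
#' @examples
#' run <- run_pipeline(seed = 1, out_dir = tempfile(), n_boot = 200)
#' run$summary
run_pipeline <- function(config = generator_config(), seed = config$seed,
                         out_dir, trials = NULL, experiments = 1:3,
                         n_boot = 2000, drop_failed_qc = TRUE,
                         policy = "subject_rank_pairing", quiet = FALSE) {
  config$seed <- as.integer(seed)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)),
            class = "fc_stage_error", parent = e)
    })
  }

  stage("simulate", {
    if (is.null(trials)) {
      trials <- generate_trials(config, experiments = experiments)
      say("simulate: %d trials across experiments %s.",
          nrow(trials), toString(experiments))
    } else {
      check_trial_columns(trials)
      say("simulate: skipped, %d supplied trials.", nrow(trials))
    }
    write_trials(trials, file.path(out_dir, "trials.csv"))
  })

  limits <- compliance_limits(
    dz_nominal = config$dz_nominal,
    fn_range = config$force_limits$normal,
    ft_range_abs = config$force_limits$tangential
  )
  qc <- stage("qc", {
    checked <- check_trials(trials, limits)
    readr::write_csv(checked, file.path(out_dir, "trials_qc.csv"), progress = FALSE)
    group <- group_compliance_tests(checked, limits)
    write_json_file(group, file.path(out_dir, "qc.json"))
    kept <- qc_filter(checked, drop_failed = drop_failed_qc, quiet = quiet)
    say("qc: %d/%d trials pass; %d group checks, %d passed.",
        sum(checked$qc_pass), nrow(checked), nrow(group), sum(group$passed))
    list(checked = checked, group = group, kept = kept)
  })

  errors <- stage("errors", {
    errs <- matching_errors(qc$kept)
    readr::write_csv(errs, file.path(out_dir, "errors.csv"), progress = FALSE)
    say("errors: %d matching errors, baseline-corrected.", nrow(errs))
    errs
  })

  summary_tbl <- stage("summary", {
    s <- summarize_conditions(errors, n_boot = n_boot, seed = derive_seed(seed, 11))
    write_json_file(s, file.path(out_dir, "summary.json"))
    say("summary: %d experiment x condition cells.", nrow(s))
    s
  })

  cues <- stage("cues", {
    conds <- intersect(c("TUP_IDN", "TDN_IUP"), unique(errors$condition))
    out <- NULL
    if (length(experiments_present(errors)) == 3) {
      out <- purrr::map(stats::setNames(conds, conds), function(cond) {
        cue_decomposition(errors, cond, policy = policy,
                          seed = derive_seed(seed, 13), n_boot = n_boot)
      })
      write_json_file(purrr::map(out, cues_as_list), file.path(out_dir, "cues.json"))
      say("cues: decomposed %s.", toString(conds))
    } else {
      say("cues: skipped (needs all three experiments).")
    }
    out
  })

  strength <- stage("strength", {
    s <- strength_of_bias(errors)
    write_json_file(s, file.path(out_dir, "strength.json"))
    say("strength: %d cells scored.", nrow(s))
    s
  })

  manifest <- stage("manifest", {
    files <- c("trials.csv", "trials_qc.csv", "qc.json", "errors.csv",
               "summary.json", "cues.json", "strength.json")
    files <- files[file.exists(file.path(out_dir, files))]
    m <- list(
      package_version = as.character(utils::packageVersion("fingercue")),
      seed = as.integer(seed),
      config = config_as_list(config),
      counts = list(trials = nrow(trials), qc_pass = sum(qc$checked$qc_pass),
                    errors = nrow(errors)),
      checksums = as.list(tools::md5sum(file.path(out_dir, files))),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    )
    names(m$checksums) <- files
    write_json_file(m, file.path(out_dir, "manifest.json"))
    m
  })

  invisible(structure(
    list(trials = qc$checked, qc = qc$group, errors = errors,
         summary = summary_tbl, cues = cues, strength = strength,
         manifest = manifest, out_dir = out_dir),
    class = "fc_run"
  ))
}

experiments_present <- function(errors) sort(unique(errors$experiment))

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$condition_effect <- apply(out$condition_effect, 1, as.list, simplify = FALSE)
  out$reps_per_condition <- as.list(out$reps_per_condition)
  out
}

cues_as_list <- function(x) {
  list(
    condition = x$condition,
    dyer_t = x$dyer_t, dyer_nt = x$dyer_nt, dyer_comb = x$dyer_comb,
    alpha_t = x$weights$alpha_t, alpha_nt = x$weights$alpha_nt,
    weights_defined = x$weights$defined,
    summed_median = x$summed_median,
    summed_ci = as.list(stats::setNames(x$summed_ci, c("low", "high"))),
    summation_z = x$summation_test$z,
    summation_p = x$summation_test$p_value,
    consistent_with_linear_summation =
      x$summation_test$consistent_with_linear_summation,
    r_exp1 = x$reliability$r_exp1, r_exp2 = x$reliability$r_exp2,
    r_exp3 = x$reliability$r_exp3,
    classification = x$reliability$classification
  )
}

#' @export
print.fc_run <- function(x, ...) {
  cat(sprintf("<fc_run> %d trials -> %d summary cells, outputs in %s\n",
              nrow(x$trials), nrow(x$summary), x$out_dir))
  invisible(x)
}

#' Verify a pipeline run against its manifest
#'
#' Recomputes the MD5 checksum of every stage output recorded in
#' `manifest.json` and reports mismatches, detecting any tampered or stale
#' intermediate file.
#'
#' @param out_dir Directory of a previous [run_pipeline()] run.
#' @return Tibble with `file`, `recorded`, `current`, `ok`.
#' @export
verify_manifest <- function(out_dir) {
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  purrr::map_dfr(names(manifest$checksums), function(f) {
    current <- unname(tools::md5sum(file.path(out_dir, f)))
    tibble::tibble(file = f, recorded = manifest$checksums[[f]],
                   current = current, ok = identical(current, manifest$checksums[[f]]))
  })
}
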