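#' Published reference values
#'
#' The condition medians and 95% CI bounds (mm), contribution weights,
#' summed-bias medians and strength-of-bias percentages reported in the
#' original study of the three matching experiments. They are shipped for
#' side-by-side display in [render_report()] only: the CI bounds, summed
#' medians and real-data z statistics depend on the study's raw dataset and
#' unstated pairing/CI conventions, so the pipeline does not attempt to
#' regenerate them.
#'
#' @return List with tibbles `medians` (experiment, condition, ci_low,
#'   median, ci_high), `weights` (condition, alpha_t), `summed` (condition,
#'   median, ci_low, ci_high) and `strength` (condition, experiment,
#'   percent, direction).
#' @export
reference_values <- function() {
  medians <- tibble::tribble(
    ~experiment, ~condition, ~ci_low, ~median, ~ci_high,
    1, "TUP_IUP", -1.77, 0.7, 0.35,
    1, "TDN_IDN", -2.63, -1.4, 0.22,
    1, "TUP_IDN", 7.59, 9.2, 10.92,
    1, "TDN_IUP", -11.59, -9.9, -8.33,
    1, "NULL", -1.06, 0.0, 1.06,
    1, "FN_ONLY", -0.75, 0.4, 1.51,
    2, "TUP_IUP", -0.69, 0.7, 2.18,
    2, "TDN_IDN", -3.98, -1.96, 0.05,
    2, "TUP_IDN", 5.72, 7.9, 10.09,
    2, "TDN_IUP", -6.90, -5.1, -3.28,
    2, "NULL", -1.45, 0.0, 1.49,
    2, "FN_ONLY", -0.87, -0.8, 2.53,
    3, "TUP_IUP", -2.54, -0.3, 1.95,
    3, "TDN_IDN", -1.98, -0.35, 1.28,
    3, "TUP_IDN", 3.29, 5.7, 8.19,
    3, "TDN_IUP", -5.99, -3.5, -0.94,
    3, "NULL", -1.33, 0.0, 1.33,
    3, "FN_ONLY", -0.96, 0.8, 2.5
  )
  weights <- tibble::tibble(condition = c("TUP_IDN", "TDN_IUP"),
                            alpha_t = c(0.58, 0.60))
  summed <- tibble::tibble(condition = c("TUP_IDN", "TDN_IUP"),
                           median = c(10.3, -10.8),
                           ci_low = c(7.4, -13.5), ci_high = c(13.3, -8.1))
  strength <- tibble::tibble(
    condition = c("TUP_IDN", "TDN_IUP", "TUP_IDN", "TDN_IUP"),
    experiment = c(2, 2, 3, 3),
    percent = c(44, 33, 20, 17),
    direction = c("positive", "negative", "positive", "negative")
  )
  list(medians = medians, weights = weights, summed = summed,
       strength = strength)
}

md_table <- function(df, digits = 4) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, digits = digits, format = "g") else as.character(x)
  }
  cells <- purrr::map(df, fmt)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- purrr::map_chr(seq_len(nrow(df)), function(i) {
    paste0("| ", paste(purrr::map_chr(cells, i), collapse = " | "), " |")
  })
  c(header, sep, rows)
}

#' Render a markdown report from pipeline outputs
#'
#' Builds a human-readable markdown summary of a [run_pipeline()] output
#' directory: condition medians with CIs and tests, cue weights and the
#' summation/reliability analysis, and the strength-of-bias residuals. With
#' `reference = TRUE`, comparison columns with the published reference
#' values ([reference_values()]) are added; these are shown for
#' side-by-side inspection only and are never used in any computation.
#' Regeneration is idempotent: the report is a pure function of the stage
#' outputs.
#'
#' @param out_dir Directory holding the pipeline outputs.
#' @param reference Add published reference columns.
#' @param path Output file (default `report.md` inside `out_dir`).
#' @return `path`, invisibly.
#' @export
render_report <- function(out_dir, reference = FALSE,
                          path = file.path(out_dir, "report.md")) {
  need <- c("summary.json", "strength.json", "manifest.json")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing) > 0)
    abort(paste0("Missing stage output(s): ", toString(missing)),
          class = "fc_stage_error")
  summary_tbl <- tibble::as_tibble(
    jsonlite::read_json(file.path(out_dir, "summary.json"), simplifyVector = TRUE))
  strength_tbl <- tibble::as_tibble(
    jsonlite::read_json(file.path(out_dir, "strength.json"), simplifyVector = TRUE))
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  cues_path <- file.path(out_dir, "cues.json")
  cues <- if (file.exists(cues_path)) jsonlite::read_json(cues_path) else NULL

  lines <- c(
    "# Matching-error analysis report",
    "",
    sprintf("Seed %s, fingercue %s, %s trials.", manifest$seed,
            manifest$package_version, manifest$counts$trials),
    "",
    "## Condition medians (mm)",
    ""
  )
  med <- summary_tbl[, c("experiment", "condition", "n", "median",
                         "ci_low", "ci_high", "wilcoxon_z", "p_value", "effect_r")]
  if (reference) {
    med <- dplyr::left_join(
      med,
      dplyr::rename(reference_values()$medians, ref_ci_low = "ci_low",
                    ref_median = "median", ref_ci_high = "ci_high"),
      by = c("experiment", "condition")
    )
  }
  lines <- c(lines, md_table(med), "")

  if (!is.null(cues)) {
    lines <- c(lines, "## Cue summation", "")
    cue_tbl <- purrr::map_dfr(cues, function(x) {
      tibble::tibble(condition = x$condition, dyer_t = x$dyer_t,
                     dyer_nt = x$dyer_nt, dyer_comb = x$dyer_comb,
                     alpha_t = x$alpha_t %||% NA_real_,
                     alpha_nt = x$alpha_nt %||% NA_real_,
                     summed_median = x$summed_median,
                     summation_p = x$summation_p,
                     classification = x$classification)
    })
    if (reference) {
      ref <- dplyr::left_join(reference_values()$weights,
                              reference_values()$summed, by = "condition")
      cue_tbl <- dplyr::left_join(
        cue_tbl,
        dplyr::rename(ref, ref_alpha_t = "alpha_t", ref_summed_median = "median",
                      ref_summed_ci_low = "ci_low", ref_summed_ci_high = "ci_high"),
        by = "condition")
    }
    lines <- c(lines, md_table(cue_tbl), "")
  }

  lines <- c(lines, "## Strength of bias", "")
  st <- strength_tbl[, c("experiment", "condition", "q1_null", "q3_null",
                         "p_pos", "p_neg", "residual")]
  if (reference) {
    ref <- reference_values()$strength[, c("experiment", "condition", "percent")]
    st <- dplyr::left_join(st, dplyr::rename(ref, ref_percent = "percent"),
                           by = c("experiment", "condition"))
  }
  lines <- c(lines, md_table(st), "")

  writeLines(lines, path)
  invisible(path)
}
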