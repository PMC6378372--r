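#' Generator configuration for synthetic matching-experiment trials
#'
#' Builds and validates the configuration object used by
#' [generate_experiment()] and [generate_trials()]. The defaults encode the
#' design of the three matching experiments: ten subjects per experiment, six
#' force conditions presented five times (Experiments 1 and 2) or six times
#' (Experiment 3), a per-subject idiosyncratic constant baseline error, and
#' condition-specific bias medians for the two opposite-direction force
#' conditions (Experiment 1: 9.2 / -9.9 mm; Experiment 2: 7.9 / -5.1 mm;
#' Experiment 3: 5.7 / -3.5 mm for `TUP_IDN` / `TDN_IUP`). Same-direction,
#' `NULL` and `FN_ONLY` conditions default to a zero effect.
#'
#' Trial noise is added to the hold-phase distance so that the configured
#' condition effect is the *median* of the generated matching errors: the
#' symmetric family is Gaussian, and the skewed families are monotone
#' transforms of a Gaussian fixed at median zero (see [rnoise()]).
#'
#' @param n_subjects Number of subjects per experiment.
#' @param reps_per_condition Named numeric vector mapping experiment
#'   (`"1"`, `"2"`, `"3"`) to repetitions per condition.
#' @param condition_effect 3 x 6 numeric matrix of median bias effects (mm);
#'   rows are experiments 1-3, columns the conditions in
#'   [force_conditions()] order. Default as described above.
#' @param subject_baseline_sd SD (mm) of the per-subject constant baseline
#'   error applied to all of a subject's trials in all conditions.
#' @param trial_noise_sd Trial-to-trial noise scale (mm); a scalar or a
#'   length-3 vector giving one value per experiment.
#' @param noise_family One of `"symmetric"`, `"right-skewed"`,
#'   `"left-skewed"`.
#' @param skew Positive skew parameter used by the skewed families.
#' @param sense_dy_jitter Half-width (mm) of the uniform jitter of the
#'   sense-phase vertical distance around 0; must not exceed 3 mm.
#' @param dz_nominal Nominal horizontal fingertip distance (mm).
#' @param dz_jitter Half-width (mm) of the uniform jitter of the sense-phase
#'   horizontal distance around `dz_nominal`; must not exceed 3 mm.
#' @param force_limits List with elements `normal` (allowed normal-force
#'   range, N) and `tangential` (allowed tangential-force magnitude range,
#'   N).
#' @param noncompliance_rate Probability that a trial violates at least one
#'   compliance window.
#' @param seed Integer master seed; per-experiment random streams are derived
#'   from it deterministically.
#'
#' @return A validated list of class `fc_config`.
#' @seealso [generate_experiment()], [read_generator_config()]
#' @export
#' @examples
#' cfg <- generator_config(seed = 42)
#' cfg$condition_effect["1", "TUP_IDN"]
generator_config <- function(n_subjects = 10,
                             reps_per_condition = c(`1` = 5, `2` = 5, `3` = 6),
                             condition_effect = default_condition_effects(),
                             subject_baseline_sd = 2,
                             trial_noise_sd = 3,
                             noise_family = c("symmetric", "right-skewed", "left-skewed"),
                             skew = 1,
                             sense_dy_jitter = 1.5,
                             dz_nominal = 65,
                             dz_jitter = 1.5,
                             force_limits = list(normal = c(4, 5), tangential = c(2.5, 3.5)),
                             noncompliance_rate = 0,
                             seed = 1L) {
  noise_family <- match.arg(noise_family)
  cfg <- structure(
    list(
      n_subjects = n_subjects,
      reps_per_condition = reps_per_condition,
      condition_effect = condition_effect,
      subject_baseline_sd = subject_baseline_sd,
      trial_noise_sd = trial_noise_sd,
      noise_family = noise_family,
      skew = skew,
      sense_dy_jitter = sense_dy_jitter,
      dz_nominal = dz_nominal,
      dz_jitter = dz_jitter,
      force_limits = force_limits,
      noncompliance_rate = noncompliance_rate,
      seed = as.integer(seed)
    ),
    class = "fc_config"
  )
  validate_config(cfg)
}

#' Default condition-effect matrix
#'
#' Median matching-error effects (mm) per experiment and force condition used
#' by the default generator configuration. Only the two opposite-direction
#' conditions carry a nonzero effect.
#'
#' @return 3 x 6 numeric matrix; rownames `"1"`-`"3"`, colnames
#'   [force_conditions()].
#' @export
default_condition_effects <- function() {
  m <- matrix(0, nrow = 3, ncol = 6,
              dimnames = list(c("1", "2", "3"), fc_conditions))
  m[, "TUP_IDN"] <- c(9.2, 7.9, 5.7)
  m[, "TDN_IUP"] <- c(-9.9, -5.1, -3.5)
  m
}

validate_config <- function(cfg) {
  bad <- function(field, why) {
    abort(sprintf("Invalid generator config: field `%s` %s.", field, why),
          class = "fc_config_error")
  }
  if (!is.numeric(cfg$n_subjects) || length(cfg$n_subjects) != 1 || cfg$n_subjects < 1)
    bad("n_subjects", "must be a single count >= 1")
  reps <- cfg$reps_per_condition
  if (!is.numeric(reps) || !all(c("1", "2", "3") %in% names(reps)))
    bad("reps_per_condition", "must be named with experiments \"1\", \"2\", \"3\"")
  if (any(reps < 1)) bad("reps_per_condition", "must be >= 1 for every experiment")
  ce <- cfg$condition_effect
  if (!is.matrix(ce) || !all(fc_conditions %in% colnames(ce)) ||
      !all(c("1", "2", "3") %in% rownames(ce)))
    bad("condition_effect", "must be a 3 x 6 matrix covering all experiments and conditions")
  for (field in c("subject_baseline_sd", "trial_noise_sd", "sense_dy_jitter", "dz_jitter")) {
    v <- cfg[[field]]
    if (!is.numeric(v) || any(v < 0)) bad(field, "must be >= 0")
  }
  if (!length(cfg$trial_noise_sd) %in% c(1L, 3L))
    bad("trial_noise_sd", "must be a scalar or one value per experiment")
  if (cfg$sense_dy_jitter > 3) bad("sense_dy_jitter", "must stay within the +/-3 mm window")
  if (cfg$dz_jitter > 3) bad("dz_jitter", "must stay within the +/-3 mm window")
  if (cfg$noncompliance_rate < 0 || cfg$noncompliance_rate > 1)
    bad("noncompliance_rate", "must be a probability in [0, 1]")
  fl <- cfg$force_limits
  if (!is.list(fl) || !all(c("normal", "tangential") %in% names(fl)) ||
      fl$normal[1] >= fl$normal[2] || fl$tangential[1] >= fl$tangential[2])
    bad("force_limits", "must hold increasing `normal` and `tangential` ranges")
  if (cfg$skew <= 0 && cfg$noise_family != "symmetric")
    bad("skew", "must be > 0 for a skewed noise family")
  cfg
}

#' Median-zero trial noise
#'
#' Draws trial-to-trial noise whose *median* is exactly zero for every
#' family, so that a location shift added to it remains the median of the
#' result. The symmetric family is Gaussian. The skewed families apply the
#' monotone map `(exp(s z) - 1) / s` to a standard Gaussian `z` (right skew
#' for `s > 0`, left for `s < 0`); because the map is increasing and fixes 0,
#' the median stays 0, and the draw is rescaled analytically to the requested
#' standard deviation.
#'
#' @param n Number of draws.
#' @param sd Target standard deviation.
#' @param family `"symmetric"`, `"right-skewed"` or `"left-skewed"`.
#' @param skew Positive skew parameter (ignored for `"symmetric"`).
#' @return Numeric vector of length `n`.
#' @export
rnoise <- function(n, sd, family = "symmetric", skew = 1) {
  if (sd == 0) return(rep(0, n))
  if (family == "symmetric") return(rnorm(n, 0, sd))
  s <- if (family == "right-skewed") abs(skew) else -abs(skew)
  z <- rnorm(n)
  y <- (exp(s * z) - 1) / s
  sd_y <- sqrt((exp(s^2) - 1) * exp(s^2)) / abs(s)
  y * sd / sd_y
}

#' Generate one synthetic matching experiment
#'
#' Simulates a full trial table for one experiment: every subject performs
#' every force condition `reps_per_condition` times. The hold-phase vertical
#' distance is `sense_dy + subject_baseline + condition_effect + noise`, so
#' the per-trial matching error (`hold_dy - sense_dy`) has the configured
#' condition effect as its median, on top of the subject's idiosyncratic
#' constant baseline. Sense-phase positions and forces are drawn inside the
#' compliance windows except for a `noncompliance_rate` fraction of trials,
#' which violate at least one window. Output is deterministic given
#' `(config, experiment)`; each experiment uses an independent random stream
#' derived from `config$seed`.
#'
#' @param config A [generator_config()] object.
#' @param experiment Experiment id: 1, 2 or 3.
#' @return A tibble with one row per trial and columns `subject_id`,
#'   `experiment`, `condition`, `repetition`, `sense_dy`, `hold_dy`,
#'   `sense_dz`, `thumb_fn`, `index_fn`, `thumb_ft`, `index_ft`, `qc_pass`
#'   (`NA` until QC is run).
#' @export
#' @examples
#' trials <- generate_experiment(generator_config(seed = 7), experiment = 1)
#' dplyr::count(trials, condition)
generate_experiment <- function(config, experiment) {
  validate_config(config)
  if (!is.numeric(experiment) || length(experiment) != 1 || !experiment %in% 1:3)
    abort(sprintf("Unknown experiment id: %s (must be 1, 2 or 3).", toString(experiment)),
          class = "fc_config_error")
  experiment <- as.integer(experiment)

  reps <- as.integer(config$reps_per_condition[[as.character(experiment)]])
  ns <- as.integer(config$n_subjects)
  noise_sd <- if (length(config$trial_noise_sd) == 3) {
    config$trial_noise_sd[[experiment]]
  } else {
    config$trial_noise_sd
  }
  fl <- config$force_limits

  with_seed(derive_seed(config$seed, experiment), {
    baseline <- rnorm(ns, 0, config$subject_baseline_sd)

    grid <- tidyr::expand_grid(
      subject = seq_len(ns),
      condition = fc_conditions,
      repetition = seq_len(reps)
    )
    n <- nrow(grid)

    effect <- unname(config$condition_effect[as.character(experiment), grid$condition])
    sense_dy <- runif(n, -config$sense_dy_jitter, config$sense_dy_jitter)
    sense_dz <- config$dz_nominal + runif(n, -config$dz_jitter, config$dz_jitter)
    noise <- rnoise(n, noise_sd, config$noise_family, config$skew)
    hold_dy <- sense_dy + baseline[grid$subject] + effect + noise

    # Compliant force draws sit well inside the windows; the margin keeps the
    # pooled group-level equivalence checks comfortably nonsignificant.
    fn_mid <- mean(fl$normal); fn_w <- diff(fl$normal) * 0.3
    ft_mid <- mean(fl$tangential); ft_w <- diff(fl$tangential) * 0.3
    thumb_fn <- runif(n, fn_mid - fn_w, fn_mid + fn_w)
    index_fn <- runif(n, fn_mid - fn_w, fn_mid + fn_w)
    sgn <- do.call(rbind, fc_tangential_sign[grid$condition])
    thumb_ft <- sgn[, "thumb"] * runif(n, ft_mid - ft_w, ft_mid + ft_w)
    index_ft <- sgn[, "index"] * runif(n, ft_mid - ft_w, ft_mid + ft_w)
    is_null <- grid$condition == "NULL"
    thumb_fn[is_null] <- 0
    index_fn[is_null] <- 0

    trials <- tibble::tibble(
      subject_id = sprintf("S%02d", grid$subject),
      experiment = experiment,
      condition = grid$condition,
      repetition = grid$repetition,
      sense_dy = sense_dy,
      hold_dy = hold_dy,
      sense_dz = sense_dz,
      thumb_fn = thumb_fn,
      index_fn = index_fn,
      thumb_ft = thumb_ft,
      index_ft = index_ft,
      qc_pass = NA
    )

    if (config$noncompliance_rate > 0) {
      viol <- which(runif(n) < config$noncompliance_rate)
      for (i in viol) trials[i, ] <- violate_trial(trials[i, ], fl)
    }
    trials
  })
}

# Make one trial breach at least one compliance window, choosing a violation
# type applicable to its condition.
violate_trial <- function(trial, fl) {
  cond <- trial$condition
  kinds <- switch(cond,
    `NULL` = "force_in_null",
    FN_ONLY = c("dy", "dz", "fn"),
    c("dy", "dz", "fn", "ft")
  )
  kind <- if (length(kinds) == 1) kinds else sample(kinds, 1)
  flip <- sample(c(-1, 1), 1)
  if (kind == "dy") {
    trial$sense_dy <- flip * runif(1, 3.5, 6)
  } else if (kind == "dz") {
    trial$sense_dz <- trial$sense_dz + flip * runif(1, 3.5, 6)
  } else if (kind == "fn") {
    trial$thumb_fn <- if (flip > 0) fl$normal[2] + runif(1, 0.3, 1) else fl$normal[1] - runif(1, 0.3, 1)
  } else if (kind == "ft") {
    s <- fc_tangential_sign[[cond]][["thumb"]]
    trial$thumb_ft <- s * (fl$tangential[1] - runif(1, 0.3, 1))
  } else { # force_in_null
    trial$thumb_fn <- runif(1, fl$normal[1], fl$normal[2])
  }
  trial
}

#' Generate all three experiments
#'
#' @param config A [generator_config()].
#' @param experiments Experiments to simulate (subset of `1:3`).
#' @return Row-bound tibble of [generate_experiment()] outputs.
#' @export
generate_trials <- function(config = generator_config(), experiments = 1:3) {
  purrr::map_dfr(experiments, function(e) generate_experiment(config, e))
}
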