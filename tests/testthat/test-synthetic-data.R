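test_that("degenerate generator (no noise, no baseline, no effects) reproduces sense exactly", {
  cfg <- quiet_config(condition_effect = matrix(
    0, 3, 6, dimnames = list(c("1", "2", "3"), force_conditions())
  ), seed = 1)
  for (e in 1:3) {
    trials <- generate_experiment(cfg, e)
    expect_equal(trials$hold_dy - trials$sense_dy, rep(0, nrow(trials)))
  }
})

test_that("generation is deterministic given (config, seed) and varies across experiments", {
  cfg <- generator_config(seed = 123)
  a <- generate_experiment(cfg, 1)
  b <- generate_experiment(cfg, 1)
  expect_identical(a, b)
  c2 <- generate_experiment(cfg, 2)
  expect_false(isTRUE(all.equal(a$hold_dy[1:10], c2$hold_dy[1:10])))
  # different seed, different draws
  d <- generate_experiment(generator_config(seed = 124), 1)
  expect_false(identical(a$hold_dy, d$hold_dy))
})

test_that("trial table has the full crossed design with correct force structure", {
  cfg <- generator_config(seed = 5)
  for (e in 1:3) {
    trials <- generate_experiment(cfg, e)
    reps <- c(5, 5, 6)[e]
    expect_equal(nrow(trials), 10 * 6 * reps)
    keys <- trials[, c("subject_id", "condition", "repetition")]
    expect_equal(anyDuplicated(keys), 0L)
    null_rows <- trials[trials$condition == "NULL", ]
    expect_true(all(null_rows$thumb_fn == 0 & null_rows$index_fn == 0 &
                      null_rows$thumb_ft == 0 & null_rows$index_ft == 0))
    fn_rows <- trials[trials$condition == "FN_ONLY", ]
    expect_true(all(fn_rows$thumb_ft == 0 & fn_rows$index_ft == 0))
    opp <- trials[trials$condition == "TUP_IDN", ]
    expect_true(all(opp$thumb_ft > 0 & opp$index_ft < 0))
  }
})

test_that("pooled large-sample error median recovers the configured effect", {
  cfg <- generator_config(n_subjects = 200, seed = 31)
  trials <- generate_experiment(cfg, 1)
  err <- trials$hold_dy - trials$sense_dy
  med <- median(err[trials$condition == "TUP_IDN"])
  expect_lt(abs(med - 9.2), 0.5)
  med2 <- median(err[trials$condition == "TDN_IUP"])
  expect_lt(abs(med2 - (-9.9)), 0.5)
})

test_that("increasing a condition effect by delta shifts the error median by delta", {
  base <- default_condition_effects()
  shifted <- base
  delta <- 4
  shifted["1", "TUP_IDN"] <- base["1", "TUP_IDN"] + delta
  cfg_a <- generator_config(n_subjects = 2000, condition_effect = base, seed = 77)
  cfg_b <- generator_config(n_subjects = 2000, condition_effect = shifted, seed = 77)
  err_med <- function(cfg) {
    tr <- generate_experiment(cfg, 1)
    median(tr$hold_dy[tr$condition == "TUP_IDN"] - tr$sense_dy[tr$condition == "TUP_IDN"])
  }
  expect_lt(abs(err_med(cfg_b) - err_med(cfg_a) - delta), 0.3)
})

test_that("noise families control skew while keeping the median at zero", {
  set.seed(42)
  sym <- rnoise(2e5, 3, "symmetric")
  expect_lt(abs(sample_skewness(sym)), 0.05)
  expect_lt(abs(median(sym)), 0.05)
  right <- rnoise(2e5, 3, "right-skewed", skew = 1)
  expect_gt(sample_skewness(right), 0.5)
  expect_lt(abs(median(right)), 0.05)
  expect_lt(abs(stats::sd(right) - 3), 0.1)
  left <- rnoise(2e5, 3, "left-skewed", skew = 1)
  expect_lt(sample_skewness(left), -0.5)
  expect_lt(abs(median(left)), 0.05)
  # skewed generator keeps the configured effect as the error median
  cfg <- generator_config(n_subjects = 400, noise_family = "right-skewed",
                          skew = 1.2, seed = 9)
  tr <- generate_experiment(cfg, 1)
  med <- median(tr$hold_dy[tr$condition == "TUP_IDN"] - tr$sense_dy[tr$condition == "TUP_IDN"])
  expect_lt(abs(med - 9.2), 0.5)
})

test_that("invalid configs and experiment ids are rejected with the offending field named", {
  expect_error(generator_config(noncompliance_rate = 1.5), "noncompliance_rate")
  expect_error(generator_config(trial_noise_sd = -1), "trial_noise_sd")
  expect_error(generator_config(reps_per_condition = c(`1` = 0, `2` = 5, `3` = 6)),
               "reps_per_condition")
  expect_error(generator_config(sense_dy_jitter = 5), "sense_dy_jitter")
  expect_error(generate_experiment(generator_config(), 4), "experiment")
})

test_that("noncompliance_rate controls the fraction of QC failures", {
  clean <- check_trials(generate_experiment(generator_config(seed = 2), 1))
  expect_true(all(clean$qc_pass))
  dirty <- check_trials(generate_experiment(
    generator_config(noncompliance_rate = 0.3, seed = 2), 1))
  frac_fail <- mean(!dirty$qc_pass)
  expect_gt(frac_fail, 0.15)
  expect_lt(frac_fail, 0.45)
  expect_true(all(nzchar(dirty$violations[!dirty$qc_pass])))
})

test_that("trial CSV round-trips field-for-field at full precision", {
  cfg <- generator_config(seed = 17)
  trials <- generate_experiment(cfg, 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(trials, path)
  back <- read_trials(path)
  expect_equal(as.data.frame(back), as.data.frame(trials))

  empty <- trials[0, ]
  write_trials(empty, path)
  expect_equal(nrow(read_trials(path)), 0L)

  one <- trials[1, ]
  write_trials(one, path)
  expect_equal(as.data.frame(read_trials(path)), as.data.frame(one))
})

test_that("structural validation rejects malformed tables; semantic breaches are flagged", {
  trials <- generate_experiment(generator_config(seed = 4), 1)
  expect_error(write_trials(trials[, -5], tempfile()), "missing columns")
  extra <- dplyr::mutate(trials, bogus = 1)
  expect_error(write_trials(extra, tempfile()), "unexpected columns")
  dup <- dplyr::bind_rows(trials, trials[1, ])
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dup, path)
  expect_error(read_trials(path), "Duplicate trial keys")

  # a NULL-condition trial with force reads back fine but breaches invariants
  bad <- trials
  i <- which(bad$condition == "NULL")[1]
  bad$thumb_fn[i] <- 4.5
  write_trials(bad, path)
  back <- read_trials(path)
  inv <- trial_invariants(back)
  expect_equal(inv$invariant, "force_in_null")
  expect_equal(inv$row, i)
  expect_equal(nrow(trial_invariants(trials)), 0L)
})

test_that("YAML config round-trips through read_generator_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_subjects: 4",
    "trial_noise_sd: 1.5",
    "noise_family: right-skewed",
    "skew: 0.8",
    "seed: 99",
    "condition_effect:",
    "  '1':",
    "    TUP_IDN: 12.0"
  ), path)
  cfg <- read_generator_config(path)
  expect_equal(cfg$n_subjects, 4)
  expect_equal(cfg$trial_noise_sd, 1.5)
  expect_equal(cfg$condition_effect["1", "TUP_IDN"], 12.0)
  expect_equal(cfg$condition_effect["2", "TUP_IDN"], 7.9) # default kept
  expect_error(read_generator_config({
    p <- withr::local_tempfile(fileext = ".yaml", .local_envir = parent.frame())
    writeLines("not_a_field: 3", p); p
  }), "Unknown generator config fields")
})
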