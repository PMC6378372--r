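test_that("cue weights reproduce known decompositions and their invariances", {
  w <- cue_weights(7.9, 5.7)
  expect_equal(round(w$alpha_t, 2), 0.58)
  expect_equal(w$alpha_t + w$alpha_nt, 1)

  expect_equal(cue_weights(4.2, 0)$alpha_t, 1)
  expect_equal(round(cue_weights(-5.1, -3.5)$alpha_t, 3), 0.593)

  set.seed(20)
  for (i in 1:25) {
    a <- runif(1, -10, 10); b <- runif(1, -10, 10)
    if (abs(a + b) < 0.1) next
    w1 <- cue_weights(a, b)
    # swapping inputs swaps the roles of the weights
    w2 <- cue_weights(b, a)
    expect_equal(w1$alpha_t, w2$alpha_nt)
    # positive rescaling leaves the weights unchanged
    k <- runif(1, 0.1, 9)
    w3 <- cue_weights(k * a, k * b)
    expect_equal(w3$alpha_t, w1$alpha_t)
  }

  undef <- cue_weights(1e-8, -1e-8)
  expect_false(undef$defined)
  expect_true(is.na(undef$alpha_t))
})

test_that("summed-bias distributions follow their pairing policies", {
  for (policy in c("subject_rank_pairing", "random_pairing", "all_pairs")) {
    expect_equal(summed_bias_distribution(3, 4, policy = policy), 7)
  }
  x <- c(1, 5, 2); y <- c(10, 20, 30, 40)
  ap <- summed_bias_distribution(x, y, policy = "all_pairs")
  expect_equal(length(ap), 12)
  expect_equal(sort(ap), sort(as.vector(outer(x, y, `+`))))

  # rank pairing on equal-length samples is the sorted elementwise sum
  a <- c(3, 1, 2); b <- c(9, 7, 8)
  expect_equal(summed_bias_distribution(a, b), sort(a) + sort(b))

  # random pairing is seeded and reproducible
  set.seed(21)
  p <- rnorm(20); q <- rnorm(30)
  r1 <- summed_bias_distribution(p, q, policy = "random_pairing", seed = 5)
  r2 <- summed_bias_distribution(p, q, policy = "random_pairing", seed = 5)
  expect_identical(r1, r2)
  expect_equal(length(r1), 20)

  # symmetric samples: median of sums tracks the sum of medians
  set.seed(22)
  s1 <- rnorm(4000, 5); s2 <- rnorm(4000, -2)
  sums <- summed_bias_distribution(s1, s2)
  expect_lt(abs(median(sums) - (median(s1) + median(s2))), 0.15)

  expect_error(summed_bias_distribution(1, numeric(0)), "non-empty")
  expect_error(summed_bias_distribution(1, 2, policy = "bogus"))
})

test_that("linear-summation test separates matched and offset samples", {
  set.seed(23)
  x <- rnorm(50, 10)
  same <- test_linear_summation(x, x)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$consistent_with_linear_summation)

  far <- test_linear_summation(x + 20, x)
  expect_lt(far$p_value, 0.001)
  expect_false(far$consistent_with_linear_summation)

  expect_error(test_linear_summation(1:3, 1:10), ">= 6")
})

test_that("reliability classification follows the inverse-variance rules exactly", {
  scale_to_var <- function(x, v) {
    x <- x - mean(x)
    x * sqrt(v / stats::var(x))
  }
  base <- c(-1.3, -0.4, 0.1, 0.2, 0.5, 0.9, 1.6, -1.6)

  # combined less reliable than both single cues: reject
  rej <- reliability_analysis(scale_to_var(base, 9),
                              scale_to_var(base, 4), scale_to_var(base, 2))
  expect_equal(rej$classification, "reject_summation")

  # combined reaches the additive bound exactly: optimal (inclusive boundary)
  v2 <- 4; v3 <- 2
  v1 <- 1 / (1 / v2 + 1 / v3)
  opt <- reliability_analysis(scale_to_var(base, v1),
                              scale_to_var(base, v2), scale_to_var(base, v3))
  expect_equal(opt$classification, "optimal_summation")
  expect_equal(opt$r_exp1, opt$r_exp2 + opt$r_exp3)

  # between the single-cue reliabilities: suboptimal linear summation
  sub <- reliability_analysis(scale_to_var(base, 3),
                              scale_to_var(base, 4), scale_to_var(base, 2))
  expect_equal(sub$classification, "suboptimal_linear_summation")
  expect_true(sub$r_exp2 < sub$r_exp1 && sub$r_exp1 < sub$r_exp3)

  # adding a constant to any sample changes nothing
  shifted <- reliability_analysis(scale_to_var(base, 3) + 100,
                                  scale_to_var(base, 4), scale_to_var(base, 2))
  expect_equal(shifted$classification, sub$classification)
  expect_equal(shifted$r_exp1, sub$r_exp1)

  expect_error(reliability_analysis(rep(1, 8), base, base), "Zero-variance")
  expect_error(reliability_analysis(1:3, base, base), ">= 6")
})

test_that("cue decomposition bundles weights, summation test and reliability coherently", {
  errs <- matching_errors(check_trials(generate_trials(generator_config(seed = 24))))
  cd <- cue_decomposition(errs, "TUP_IDN", n_boot = 300, seed = 2)
  expect_s3_class(cd, "fc_cues")
  expect_equal(cd$dyer_t,
               median(errs$corrected_error[errs$experiment == 2 &
                                             errs$condition == "TUP_IDN"]))
  expect_equal(cd$weights$alpha_t,
               cue_weights(cd$dyer_t, cd$dyer_nt)$alpha_t)
  expect_equal(length(cd$summed_sample), 50)
  expect_lte(cd$summed_ci[1], cd$summed_median)
  expect_gte(cd$summed_ci[2], cd$summed_median)
  expect_true(cd$reliability$classification %in%
                c("optimal_summation", "suboptimal_linear_summation",
                  "reject_summation"))

  td <- tidy(cd)
  expect_equal(nrow(td), 1)
  expect_named(td, c("condition", "dyer_t", "dyer_nt", "dyer_comb", "alpha_t",
                     "alpha_nt", "weights_defined", "summed_median",
                     "summed_ci_low", "summed_ci_high", "summation_z",
                     "summation_p", "consistent_with_linear_summation",
                     "r_exp1", "r_exp2", "r_exp3", "classification"))
  gl <- glance(cd)
  expect_equal(gl$condition, "TUP_IDN")

  wt <- wilcoxon_signed_rank(rnorm(20) + 1)
  expect_named(tidy(wt), c("name", "statistic", "z", "p_value", "n",
                           "tails", "method", "degenerate"))
})
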