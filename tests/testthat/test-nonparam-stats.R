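# Independent oracle: exact signed-rank tail probability by explicit
# enumeration of all 2^n sign assignments.
brute_signed_rank_p <- function(values, mu = 0, alternative = "greater") {
  d <- values - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  switch(alternative,
    greater = mean(w_all >= w_obs),
    less = mean(w_all <= w_obs),
    two.sided = min(1, 2 * min(mean(w_all >= w_obs), mean(w_all <= w_obs)))
  )
}

# Independent oracle: hand-ranked Kruskal-Wallis H with tie correction.
hand_rank_H <- function(groups) {
  values <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  h <- 12 / (n * (n + 1)) * sum(lengths(groups) * (rbar - (n + 1) / 2)^2)
  tie_tab <- table(r)
  h / (1 - sum(tie_tab^3 - tie_tab) / (n^3 - n))
}

test_that("exact signed-rank p-values match closed forms and the 2^n enumeration oracle", {
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6) / 10, alternative = "greater")
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 1 / 64)

  set.seed(7)
  for (i in 1:200) {
    n <- sample(5:10, 1)
    x <- round(rnorm(n, sd = 3) + runif(1, -1, 1), 3)
    x <- x[x != 0]
    if (length(x) < 5 || any(duplicated(abs(x)))) next
    alt <- sample(c("greater", "less", "two.sided"), 1)
    expect_equal(wilcoxon_signed_rank(x, alternative = alt)$p_value,
                 brute_signed_rank_p(x, alternative = alt))
  }
})

test_that("exact signed-rank p agrees with the reference implementation and is scale-invariant", {
  set.seed(8)
  for (i in 1:50) {
    x <- rnorm(sample(6:12, 1)) + 0.3
    if (any(duplicated(abs(x))) || any(x == 0)) next
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(wilcoxon_signed_rank(x, alternative = alt)$p_value,
                   stats::wilcox.test(x, alternative = alt, exact = TRUE)$p.value)
    }
    c_pos <- runif(1, 0.1, 10)
    expect_equal(wilcoxon_signed_rank(c_pos * x)$p_value,
                 wilcoxon_signed_rank(x)$p_value)
  }
})

test_that("signed-rank z is signed by the effect; symmetric samples give p near 1", {
  up <- wilcoxon_signed_rank(rnorm(30) + 2)
  expect_gt(up$z, 0)
  dn <- wilcoxon_signed_rank(rnorm(30) - 2)
  expect_lt(dn$z, 0)
  sym <- wilcoxon_signed_rank(c(-3, 3, -2, 2, -1, 1, -0.5, 0.5))
  expect_equal(sym$z, 0)
  expect_equal(sym$p_value, 1)
  zeros <- wilcoxon_signed_rank(rep(0, 10))
  expect_true(zeros$degenerate)
  expect_equal(zeros$p_value, 1)
})

test_that("normal approximation tracks the exact signed-rank p closely at n = 10", {
  set.seed(9)
  worst <- 0
  for (i in 1:1000) {
    x <- rnorm(10) + runif(1, -1, 1)
    if (any(duplicated(abs(x))) || any(x == 0)) next
    pe <- wilcoxon_signed_rank(x, alternative = "two.sided")$p_value
    pa <- wilcoxon_signed_rank(x, alternative = "two.sided", exact_cutoff = 0)$p_value
    worst <- max(worst, abs(pe - pa))
  }
  expect_lt(worst, 0.03)
})

test_that("Kruskal-Wallis H matches the hand-rank formula and the reference implementation", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  res <- kruskal_wallis(g)
  expect_equal(res$statistic, hand_rank_H(g))
  expect_equal(res$df, 2)

  set.seed(10)
  for (i in 1:100) {
    groups <- purrr::map(1:3, ~ round(rnorm(sample(3:8, 1), sd = 2), 1))
    if (stats::sd(unlist(groups)) == 0) next
    res <- kruskal_wallis(groups)
    expect_equal(res$statistic, hand_rank_H(groups))
    ref <- stats::kruskal.test(unlist(groups),
                               factor(rep(seq_along(groups), lengths(groups))))
    expect_equal(res$p_value, ref$p.value)
  }
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms and handles identical groups", {
  ident <- kruskal_wallis(list(rep(1, 4), rep(1, 5), rep(1, 4)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_true(ident$degenerate)

  set.seed(11)
  groups <- purrr::map(1:4, ~ rnorm(6))
  h1 <- kruskal_wallis(groups)$statistic
  h2 <- kruskal_wallis(purrr::map(groups, ~ exp(3 * .x) - 1))$statistic
  expect_equal(h1, h2)

  expect_error(kruskal_wallis(list(1:3, 4)), "at least 2 values")
  expect_error(kruskal_wallis(list(1:3)), "at least 2 groups")
})

test_that("Dunn post-hoc contrasts order by separation and adjustment is monotone", {
  ident <- posthoc_pairwise(list(a = rep(1, 5), b = rep(1, 5), c = rep(1, 5)))
  expect_equal(ident$p_adjusted, rep(1, 3))

  set.seed(12)
  groups <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8) + 50)
  res <- posthoc_pairwise(groups)
  involves_c <- res$group1 == "c" | res$group2 == "c"
  expect_true(max(res$p_value[involves_c]) < min(res$p_value[!involves_c]))
  expect_true(all(res$p_adjusted >= res$p_value))
  bonf <- posthoc_pairwise(groups, method = "bonferroni")
  expect_true(all(bonf$p_adjusted >= bonf$p_value))
})

test_that("effect size r is |z|/sqrt(n), clipped to [0, 1]", {
  expect_equal(effect_size_r(0, 50), 0)
  expect_equal(round(effect_size_r(6.02, 55), 2), 0.81)
  expect_equal(round(effect_size_r(3.47, 55), 2), 0.47)
  expect_equal(round(effect_size_r(-3.84, 55), 2), 0.52)
  expect_equal(effect_size_r(10, 4), 1)
  expect_error(effect_size_r(1, 0), "`n` must be > 0")
})

test_that("one-tailed signed-rank test holds its nominal level on independent nulls", {
  set.seed(13)
  rejections <- mean(replicate(2000, {
    wilcoxon_signed_rank(rnorm(50), alternative = "greater")$p_value < 0.05
  }))
  expect_gt(rejections, 0.03)
  expect_lt(rejections, 0.07)
})

test_that("rank-sum z/p matches the reference normal-approximation implementation", {
  set.seed(15)
  for (i in 1:50) {
    x <- rnorm(sample(8:40, 1)) + runif(1, -1, 1)
    y <- rnorm(sample(8:40, 1))
    res <- rank_sum_test(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(res$p_value, ref$p.value)
  }
  same <- rank_sum_test(1:10, 1:10)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
})

test_that("fatigue correlation flags drift with repetition and nothing else", {
  drift <- purrr::map_dfr(1:10, function(s) {
    make_subject_errors(sprintf("S%02d", s), 2,
                        list(`NULL` = rep(0, 5), TUP_IDN = 1:5))
  })
  res <- fatigue_correlation(matching_errors(drift), conditions = "TUP_IDN")
  expect_equal(res$pearson_r, 1)

  anti <- purrr::map_dfr(1:10, function(s) {
    make_subject_errors(sprintf("S%02d", s), 2,
                        list(`NULL` = rep(0, 5), TUP_IDN = -(1:5)))
  })
  res2 <- fatigue_correlation(matching_errors(anti), conditions = "TUP_IDN")
  expect_equal(res2$pearson_r, -1)

  flat <- purrr::map_dfr(1:10, function(s) {
    make_subject_errors(sprintf("S%02d", s), 2,
                        list(`NULL` = rep(0, 5), TUP_IDN = rep(2, 5)))
  })
  res3 <- fatigue_correlation(matching_errors(flat), conditions = "TUP_IDN")
  expect_true(res3$degenerate)

  # repetition-independent generator errors: drift is absent in most seeds
  ok <- purrr::map_lgl(1:100, function(seed) {
    errs <- matching_errors(generate_experiment(generator_config(seed = 2000 + seed), 2))
    all(fatigue_correlation(errs)$p_value > 0.05)
  })
  expect_gte(mean(ok), 0.85)
})
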