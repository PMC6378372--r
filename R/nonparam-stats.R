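#' Nonparametric test results
#'
#' All tests in the package return an `fc_test` object: a light list with
#' fields `name`, `statistic`, `z`, `p_value`, `n`, `tails`, `method` and
#' `degenerate`, plus test-specific extras (`df` for Kruskal-Wallis,
#' `consistent_with_linear_summation` for the summation test). Use [tidy()]
#' to get a one-row tibble.
#'
#' @name fc_test
NULL

new_fc_test <- function(name, statistic, z, p_value, n, tails, method,
                        degenerate = FALSE, ...) {
  structure(
    list(name = name, statistic = statistic, z = z,
         p_value = p_value, n = n, tails = tails, method = method,
         degenerate = degenerate, ...),
    class = "fc_test"
  )
}

#' @export
print.fc_test <- function(x, ...) {
  cat(sprintf("<fc_test> %s (%s, %s-tailed)\n", x$name, x$method, x$tails))
  cat(sprintf("  statistic = %.4g, z = %s, p = %.4g, n = %d%s\n",
              x$statistic, ifelse(is.na(x$z), "NA", sprintf("%.3f", x$z)),
              x$p_value, x$n,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Wilcoxon signed-rank test
#'
#' One-sample signed-rank test of location against `mu`. The p-value is
#' computed by full enumeration of the null distribution of the positive-rank
#' sum when the sample has at most `exact_cutoff` nonzero differences and no
#' ties in their absolute values; otherwise a normal approximation with
#' mid-rank tie correction and continuity correction is used. The reported
#' `z` always carries the sign of the observed effect (positive when values
#' tend to exceed `mu`). All-zero differences yield `p = 1` with a
#' `degenerate` flag.
#'
#' @param values Numeric sample.
#' @param mu Null location.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param exact_cutoff Largest `n` for which the exact enumeration is used.
#' @param name Label stored in the result.
#' @return An [fc_test] object; `statistic` is the positive-rank sum `W+`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1.2, 0.8, 2.1, 1.7, 0.4, 1.1), alternative = "greater")
wilcoxon_signed_rank <- function(values, mu = 0,
                                 alternative = c("two.sided", "greater", "less"),
                                 exact_cutoff = 12,
                                 name = "wilcoxon_signed_rank") {
  alternative <- match.arg(alternative)
  if (any(!is.finite(values))) abort("Non-finite values in sample.", class = "fc_stat_error")
  d <- values - mu
  d <- d[d != 0]
  n <- length(d)
  tails <- if (alternative == "two.sided") "two" else "one"
  if (n == 0) {
    return(new_fc_test("wilcoxon_signed_rank", NA_real_, 0, 1, length(values),
                       tails, "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ew <- n * (n + 1) / 4
  tie_tab <- table(r)
  vw <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  # Signed, continuity-corrected z (reported for every method).
  cc <- 0.5 * sign(w - ew)
  z <- if (vw > 0) (w - ew - cc) / sqrt(vw) else 0

  ties <- any(duplicated(abs(d)))
  if (n <= exact_cutoff && !ties) {
    dist <- signed_rank_distribution(n)
    p_ge <- sum(dist[(w + 1):length(dist)])
    p_le <- sum(dist[1:(w + 1)])
    p <- switch(alternative,
      greater = p_ge,
      less = p_le,
      two.sided = min(1, 2 * min(p_ge, p_le))
    )
    method <- "exact"
  } else {
    sdw <- sqrt(vw)
    p <- switch(alternative,
      greater = pnorm((w - ew - 0.5) / sdw, lower.tail = FALSE),
      less = pnorm((w - ew + 0.5) / sdw),
      two.sided = 2 * pnorm(-abs(z))
    )
    p <- min(1, max(0, p))
    method <- "normal_approx"
  }
  new_fc_test(name, w, z, p, n, tails, method)
}

# Null pmf of the positive-rank sum W+ for n untied observations, over
# support 0..n(n+1)/2, built by dynamic programming over ranks.
signed_rank_distribution <- function(n) {
  m <- n * (n + 1) / 2
  counts <- c(1, rep(0, m))
  for (k in seq_len(n)) {
    shifted <- c(rep(0, k), counts[1:(m + 1 - k)])
    counts <- counts + shifted
  }
  counts / 2^n
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Normal-approximation rank-sum (Mann-Whitney) test with mid-rank tie
#' correction and continuity correction; `z` carries the sign of the location
#' difference of `x` relative to `y`.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return An [fc_test]; `statistic` is the rank sum of `x`.
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (nx == 0 || ny == 0) abort("Both samples must be non-empty.", class = "fc_stat_error")
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(nx)])
  ew <- nx * (n + 1) / 2
  tie_tab <- table(r)
  vw <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  tails <- if (alternative == "two.sided") "two" else "one"
  if (vw <= 0) {
    return(new_fc_test("rank_sum", w, 0, 1, n, tails, "degenerate", degenerate = TRUE))
  }
  sdw <- sqrt(vw)
  z <- (w - ew - 0.5 * sign(w - ew)) / sdw
  p <- switch(alternative,
    greater = pnorm((w - ew - 0.5) / sdw, lower.tail = FALSE),
    less = pnorm((w - ew + 0.5) / sdw),
    two.sided = 2 * pnorm(-abs(z))
  )
  new_fc_test("rank_sum", w, z, min(1, p), n, tails, "normal_approx")
}

# Normalise group input: a list of numeric vectors, or a data frame with
# `value` and `group` columns.
as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("value", "group") %in% names(groups)))
      abort("Data-frame input needs `value` and `group` columns.", class = "fc_stat_error")
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups) || length(groups) < 2)
    abort("Need at least 2 groups.", class = "fc_stat_error")
  groups
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' `k - 1` degrees of freedom (computed via [stats::kruskal.test()]).
#'
#' @param groups A list of numeric vectors, or a data frame with `value` and
#'   `group` columns.
#' @return An [fc_test] with extra field `df`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_group_list(groups)
  if (any(lengths(groups) < 2))
    abort("Every group needs at least 2 values.", class = "fc_stat_error")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::sd(values) == 0) {
    return(new_fc_test("kruskal_wallis", 0, NA_real_, 1, length(values),
                       "two", "chi_square", degenerate = TRUE,
                       df = length(groups) - 1))
  }
  kt <- stats::kruskal.test(values, g)
  new_fc_test("kruskal_wallis", unname(kt$statistic), NA_real_,
              kt$p.value, length(values), "two", "chi_square",
              df = unname(kt$parameter))
}

#' Dunn's post-hoc pairwise contrasts
#'
#' Pairwise z contrasts on the pooled mid-ranks following a Kruskal-Wallis
#' test, with tie correction; p-values are two-sided and adjusted for
#' multiplicity.
#'
#' @param groups As in [kruskal_wallis()].
#' @param method Adjustment: `"holm"` (default), `"bonferroni"` or `"none"`.
#' @return Tibble with one row per pair: `group1`, `group2`, `z`, `p_value`,
#'   `p_adjusted`, `n1`, `n2`.
#' @export
posthoc_pairwise <- function(groups, method = c("holm", "bonferroni", "none")) {
  method <- match.arg(method)
  groups <- as_group_list(groups)
  labs <- names(groups) %||% as.character(seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, rep(seq_along(groups), lengths(groups)), mean)
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) / 12 - sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(sigma2 * (1 / lengths(groups)[i] + 1 / lengths(groups)[j]))
    z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    tibble::tibble(group1 = labs[i], group2 = labs[j], z = z,
                   p_value = 2 * pnorm(-abs(z)),
                   n1 = lengths(groups)[[i]], n2 = lengths(groups)[[j]])
  })
  res$p_adjusted <- p.adjust(res$p_value, method = method)
  res[, c("group1", "group2", "z", "p_value", "p_adjusted", "n1", "n2")]
}

#' Cohen's r effect size from a z statistic
#'
#' `r = |z| / sqrt(n)`, clipped to `[0, 1]` — the effect size of a one-sample
#' nonparametric test obtained by dividing the test statistic by the square
#' root of the number of observations.
#'
#' @param z Standardised test statistic.
#' @param n Number of observations (> 0).
#' @return Numeric in `[0, 1]`.
#' @export
#' @examples
#' effect_size_r(6.02, 55)
effect_size_r <- function(z, n) {
  if (any(n <= 0)) abort("`n` must be > 0.", class = "fc_stat_error")
  pmin(1, abs(z) / sqrt(n))
}

#' Matching error as a function of repetition (fatigue check)
#'
#' Tests, per experiment and condition, whether the matching error drifts
#' with the repetition index — the signature muscle fatigue (or thixotropy)
#' would leave. Trials are pooled across subjects and ordered by repetition
#' (all subjects' first repetitions, then all second repetitions, and so on);
#' a Pearson correlation of error against repetition index and the regression
#' slope p-value are reported.
#'
#' @param errors Matching-error tibble (see [matching_errors()]); uses
#'   `corrected_error` when present, else `raw_error`.
#' @param conditions Conditions to test; defaults to the two
#'   opposite-direction conditions.
#' @return Tibble with `experiment`, `condition`, `n`, `pearson_r`,
#'   `p_value`, `degenerate`.
#' @export
fatigue_correlation <- function(errors, conditions = c("TUP_IDN", "TDN_IUP")) {
  value_col <- if ("corrected_error" %in% names(errors) &&
                  !all(is.na(errors$corrected_error))) "corrected_error" else "raw_error"
  errors |>
    dplyr::filter(.data$condition %in% conditions) |>
    dplyr::group_by(.data$experiment, .data$condition) |>
    dplyr::group_modify(function(df, key) {
      if (dplyr::n_distinct(df$repetition) < 3)
        abort("Need at least 3 repetitions for the fatigue check.",
              class = "fc_stat_error")
      v <- df[[value_col]]
      if (stats::sd(v) == 0) {
        return(tibble::tibble(n = nrow(df), pearson_r = NA_real_,
                              p_value = NA_real_, degenerate = TRUE))
      }
      ct <- stats::cor.test(v, df$repetition, method = "pearson")
      tibble::tibble(n = nrow(df), pearson_r = unname(ct$estimate),
                     p_value = ct$p.value, degenerate = FALSE)
    }) |>
    dplyr::ungroup()
}
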