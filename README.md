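# fingercue

Analysis of how force-related **tactile** (finger-pad compression and skin
stretch) and **non-tactile** (efference copy plus muscle/joint
proprioception) inputs bias the estimation of fingertip relative position,
for researchers in haptics and sensorimotor psychophysics.

The modelled design: subjects sense a vertical thumb–index distance
`d_y ≈ 0` under one of six digit-force conditions and later reproduce it
from memory. The **matching error** `Dyer = d_y(hold) − d_y(sense)` (mm,
positive = thumb reproduced higher) is the bias measure. Three ten-subject
experiments separate the inputs — combined (Exp. 1), tactile-only
(Exp. 2), non-tactile-only (Exp. 3) — and the core model is linear cue
summation:

```
Dyer_comb = Dyer_t + Dyer_nt
alpha_t   = Dyer_t / (Dyer_t + Dyer_nt),   alpha_nt = 1 − alpha_t
```

with an inverse-variance reliability check (`r = 1/σ²`; optimal fusion
iff `r_comb ≥ r_t + r_nt`) and a quartile-exceedance **strength-of-bias**
statistic (probability that condition errors leave the Null-condition
interquartile band, baseline-subtracted per subject, positive minus
negative residual).

The package provides, as tidyverse-style data-frame-in/tibble-out
functions:

* a seeded synthetic-trial generator emulating the three experiments
  (`generator_config()`, `generate_trials()`);
* sense-phase compliance QC (`check_trials()`,
  `group_compliance_tests()`);
* matching errors with per-subject Null-baseline correction and bootstrap
  condition summaries (`matching_errors()`, `summarize_conditions()`);
* a nonparametric kernel: exact/approximate Wilcoxon signed-rank,
  Kruskal–Wallis, Dunn post-hoc contrasts, `r = |z|/√n` effect sizes, and
  a fatigue (error-vs-repetition) check;
* the cue-summation analysis (`cue_decomposition()`, `cue_weights()`,
  `reliability_analysis()`) and strength of bias (`strength_of_bias()`);
* an end-to-end reproducible pipeline with manifests
  (`run_pipeline()`, `render_report()`), `autoplot()` methods and
  broom-style `tidy()`/`glance()`.

## Worked example

```r
library(fingercue)

run <- run_pipeline(seed = 1, out_dir = "results")
dplyr::filter(run$summary, condition %in% c("TUP_IDN", "TDN_IUP"))
#>   experiment condition  n median ci_low ci_high wilcoxon_z  p_value effect_r
#> 1          1   TUP_IDN 50   9.80   8.97   10.82       6.15 3.90e-10    0.870
#> 2          1   TDN_IUP 50 -10.26 -11.20   -9.12      -6.15 3.90e-10    0.870
#> 3          2   TUP_IDN 50   8.05   6.89    9.25       6.15 3.90e-10    0.870
#> 4          2   TDN_IUP 50  -5.27  -6.30   -4.61      -6.13 4.40e-10    0.867
#> 5          3   TUP_IDN 60   4.55   3.94    5.84       6.42 7.01e-11    0.828
#> 6          3   TDN_IUP 60  -3.39  -4.27   -2.43      -5.91 1.73e-09    0.763

run$cues$TUP_IDN
#> <fc_cues> condition TUP_IDN
#>   medians (mm): tactile 8.05, non-tactile 4.55, combined 9.80
#>   weights: alpha_t = 0.64, alpha_nt = 0.36
#>   summed median 12.60 mm (95% CI 10.81, 15.07); rank-sum p = 0.000 (summation rejected)
#>   reliability: suboptimal_linear_summation
```

Reading the output: the opposite-direction conditions show large biases in
the thumb-force direction (≈ ±10 mm combined), shrinking when each input
acts alone; the tactile share of the summed bias is `alpha_t`. On this
default synthetic dataset the generator encodes the published
*non-additive* medians (9.2 vs 7.9 + 5.7 mm), so the rank-sum test
rightly flags the summed distribution as exceeding the combined one —
regenerate with an additive effect matrix to see the consistent case. The
strength-of-bias residuals for the same run:

```r
dplyr::filter(run$strength, experiment == 2)[, c("condition", "p_pos", "p_neg", "residual")]
#>   condition p_pos p_neg residual
#> 1   TUP_IUP  0.04  0.08    -0.04
#> 2   TDN_IDN  0.00  0.02    -0.02
#> 3   TUP_IDN  0.68 -0.26     0.94
#> 4   TDN_IUP -0.26  0.60    -0.86
#> 5      NULL  0.00  0.00     0.00
#> 6   FN_ONLY -0.12 -0.02    -0.10
```

Only the opposite-direction conditions push errors consistently outside
the Null interquartile band. `autoplot(run$summary)`,
`autoplot(run$strength)` and `render_report("results", reference = TRUE)`
give the graphical and tabular views; the `reference = TRUE` mode adds the
published values for side-by-side display only.

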