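---
title: "Methods: cue summation in fingertip distance estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cue summation in fingertip distance estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fingercue)
```

## The scientific problem

When the thumb and index finger press on a surface, force-related signals
bias the perceived vertical distance between the two fingertips: with the
thumb pushing up and the index finger pushing down, people reproduce the
thumb as sitting several millimetres *higher* than it was. The bias can be
driven by two families of input: **tactile** signals from finger-pad
compression and skin stretch, and **non-tactile** signals — the efference
copy of the motor command plus muscle/joint proprioception. The experimental
logic this package models isolates them in three matching experiments with
separate ten-subject groups:

* **Experiment 1** — both inputs (voluntary digit forces on an instrumented
  handle);
* **Experiment 2** — tactile only (wearable haptic devices stimulate the
  passive finger pads);
* **Experiment 3** — non-tactile only (forces exerted against device
  endpoints strapped to the phalanges, sparing the finger pads).

Each trial has a *sense* phase, where the subject experiences a vertical
fingertip distance `d_y` near zero under one of six force conditions, and a
*hold* phase, where the remembered distance is reproduced. The **matching
error** is `hold d_y − sense d_y` (mm, positive = thumb reproduced higher).
The six conditions cross the tangential force directions at the two digits:
same-direction (`TUP_IUP`, `TDN_IDN`), opposite-direction (`TUP_IDN`,
`TDN_IUP` — the illusion-eliciting ones), no force (`NULL`) and normal force
only (`FN_ONLY`).

## The analysis pipeline

`run_pipeline()` chains the stages; each is exported on its own.

**Compliance QC** (`check_trials()`, `group_compliance_tests()`). The
protocol requires sense-phase `d_y` within 0 ± 3 mm, horizontal distance
`d_z` within 65 ± 3 mm, normal forces in 4–5 N and tangential magnitudes in
2.5–3.5 N with condition-prescribed directions. Per-trial checks produce
`qc_pass` plus violation labels; group-level checks run, per condition and
variable, *two one-sided* Wilcoxon signed-rank tests against the window
bounds, passing when neither bound is systematically exceeded
(`p > 0.05` on both sides). The group-null wording ("not statistically
different than the thresholds") does not fix a direction; the two one-sided
reading is the one that matches "always within the target range". Trials
failing QC are dropped by default (switchable): the original analysis
verified compliance without stating exclusions, and dropping is the
conservative choice for a generator that can inject violations.

**Matching errors and baseline correction** (`matching_errors()`). Subjects
carry idiosyncratic constant biases (finger geometry, perceptual offsets),
so the per-subject **mean** of `NULL`-condition errors is subtracted from
all of that subject's errors, `NULL` included. The mean (not the median) is
used because the correction is described as subtracting the *mean* control
error; `center = "median"` is available. With the mean, correction is
exactly idempotent and per-subject corrected `NULL` errors are centred on
zero.

**Condition summaries** (`summarize_conditions()`). Per experiment ×
condition cell: median; 95% percentile bootstrap CI of the median over
trials (seeded, `n_boot = 2000` by default); a one-tailed Wilcoxon
signed-rank test against zero whose direction follows the sign of the
observed median (two-sided when the median is exactly zero); and Cohen's
`r = |z|/sqrt(n)`. The CI method is a deliberate choice — the original
report does not name its CI construction, so its printed CI bounds are not
reproducible digit-for-digit and are shipped only as display references
(`reference_values()`).

**Nonparametric kernel** (`wilcoxon_signed_rank()`, `kruskal_wallis()`,
`posthoc_pairwise()`, `effect_size_r()`, `fatigue_correlation()`). The
signed-rank test enumerates the exact null distribution of the
positive-rank sum when there are at most 12 untied nonzero differences
(dynamic programming over ranks; the cutoff keeps enumeration exact yet
cheap), and otherwise uses the normal approximation with mid-rank tie
correction and continuity correction; `z` always carries the effect sign so
that effect sizes and one-tailed directions are well defined.
Kruskal–Wallis delegates to `stats::kruskal.test` behind the package's
result type; post-hoc contrasts are Dunn's z tests on pooled ranks with
Holm adjustment by default (the adjustment is switchable; no installed
package provides Dunn's test, so it is implemented here). The fatigue check
correlates trial-level corrected errors with the repetition index per
condition — a drift would be the signature of muscle fatigue or thixotropy
contaminating the bias.

**Cue summation** (`cue_decomposition()`). Under linear summation the
combined bias equals the sum of the single-cue biases. The package
computes:

* contribution weights `alpha_t = Dyer_t / (Dyer_t + Dyer_nt)`,
  `alpha_nt = 1 − alpha_t` from the tactile-only and non-tactile-only cell
  medians (undefined, flagged, when the denominator is within `1e-6` mm of
  zero);
* a **summed-bias distribution**: the two single-cue samples come from
  different subject groups, so no canonical trial pairing exists. The
  default pairs the sorted samples by rank (`subject_rank_pairing`);
  `random_pairing` (seeded) and `all_pairs` are provided so the pairing
  sensitivity is visible rather than hidden. Rank pairing is the default
  because it is deterministic and preserves the location structure of both
  margins; note it is a comonotone coupling, so it *maximises* the spread
  of the sums — conclusions about the summed median are insensitive to
  this, spread-based conclusions are not;
* a two-sample Wilcoxon rank-sum comparison of the summed sample against
  the combined-input errors (`p > 0.05` read as consistent with linear
  summation);
* an inverse-variance **reliability triple**: `r = 1/var` per experiment.
  Classification: `reject_summation` when the combined estimate is less
  reliable than both single cues; `optimal_summation` when it reaches the
  additive maximum-likelihood bound `r_1 ≥ r_2 + r_3` (inclusive);
  `suboptimal_linear_summation` between. The additive bound is the standard
  optimal-fusion benchmark; the original report describes the regions only
  verbally.

**Strength of bias** (`strength_of_bias()`). For each experiment the pooled
corrected `NULL` errors define an interquartile band `(q1, q3)` — linear
interpolation quantiles (R type 7), switchable because at 50 trials the
quartile definition visibly moves the band. Per subject, the fractions of
condition trials above `q3` and below `q1` are computed, the subject's own
`NULL` exceedance fractions are subtracted (individual-differences
correction), subjects are averaged, and the signed residual is
`p_pos − p_neg`. Pooled-trial variants are reported alongside because the
published percentages do not disambiguate subject-averaged from
pooled-trial fractions; the two coincide when repetition counts are equal.
The two-level construction — pooled quartiles, per-subject baseline
subtraction — is the reading that reconciles the pooled "50 trials" framing
with the per-subject correction.

## The synthetic-data generator

`generator_config()` + `generate_experiment()` emulate the statistical
structure of the three experiments so that every stage is testable without
the archived raw data:

* 10 subjects × 6 conditions × 5 repetitions (experiments 1–2) or 6
  (experiment 3);
* `hold_dy = sense_dy + subject_baseline + condition_effect + noise`;
* default condition effects are the published opposite-condition medians
  (9.2/−9.9, 7.9/−5.1, 5.7/−3.5 mm); same-direction, `NULL` and `FN_ONLY`
  default to zero, matching the finding that those cells are not
  statistically different from zero;
* subject baselines are constant offsets (`sd` 2 mm) applied to *all* of a
  subject's trials — they exist precisely so the Null-baseline correction
  has something real to remove;
* trial noise defaults to symmetric Gaussian, `sd` 3 mm. That scale makes
  the generated cell medians land inside the published CI widths
  (≈ ±1.5–2.5 mm at n = 50) and the noise is attached to the hold phase
  because the sense phase is clamped by the ±3 mm protocol window. Skewed
  options apply a monotone zero-fixing transform of a Gaussian, so the
  configured effect remains the *median* — every published summary is a
  median, so location must be median-true under skew;
* sense-phase positions and forces are drawn inside the compliance windows
  (uniform, at 30% margin from the bounds) except for a configurable
  `noncompliance_rate` fraction of trials that violate at least one window;
* one integer seed; per-experiment streams are derived deterministically,
  so a table is byte-reproducible from `(config, seed)`.

What the generator does **not** emulate: time-resolved force/position
profiles within a trial, biomechanics of skin or devices, the audible
warning used in experiment 3, and — importantly — the error-distribution
*shape* of the real data. The published summed-bias medians (10.3 and
−10.8 mm) differ from the sums of the printed single-cue medians
(13.6, −8.6 mm), which implies skew and/or a specific subject pairing in
the real data that is not documented; skew is therefore left configurable
rather than fixed, and those two numbers are treated as display-only
references. Passing tests on synthetic data show the *machinery* is
correct under the stated statistical structure, not that real data satisfy
that structure.

## Numerical choices and degenerate inputs

* Quantiles and bootstrap percentiles: R type 7 throughout, switchable
  where it matters scientifically (`null_quartiles()`).
* Wilcoxon: `exact_cutoff = 12`; all-zero difference sets return `p = 1`
  flagged `degenerate` rather than erroring, so wholesale-degenerate cells
  surface in summaries instead of aborting pipelines.
* Constant cells: CIs collapse to a point and are flagged; zero-variance
  samples make reliabilities undefined and error loudly.
* Weight denominator tolerance: `1e-6` mm.
* Seeds: a master seed plus fixed multipliers derives per-stage streams
  (kept below 2^31); no stage consumes the global RNG state.

## Known limitations

The baseline correction subtracts a per-subject *estimate* (the mean of
five `NULL` trials), which leaves a shared noise term in all of a subject's
corrected errors (intra-class correlation ≈ 1/6, variance inflation ≈ 1.67
for cluster-level statistics). Two consequences, both properties of the
modelled analysis itself and visible in this package's simulations:

* the pooled n = 50 trial-level bootstrap CI of the median undercovers
  slightly (≈ 88–95% instead of 95% across the headline cells; a
  subject-level bootstrap is no remedy with only ten clusters);
* the pooled one-tailed Wilcoxon against zero, with the tail chosen from
  the observed median sign, has a false-positive rate near 0.16–0.21 for
  truly zero-effect cells rather than the nominal ≈ 0.10. A single
  dataset's "all p > 0.05" for those cells is thus an ~80%-probability
  event, not a near-certain one.

Neither issue affects the headline recovery of the condition medians, the
cue weights, or the strength-of-bias ordering, all of which reproduce
stably (see `scripts/acceptance.R`).

Problem sizes used by the shipped test-suite simulations: 100-seed sweeps
for coverage/level checks, 15–40 seeds for ordering and consistency checks,
2000 bootstrap replicates (10,000 where stability itself is under test),
and up to 2000 synthetic subjects for location-recovery checks.

## A worked example

```{r example, eval = FALSE}
library(fingercue)

run <- run_pipeline(seed = 1, out_dir = "results")
run$summary[run$summary$condition == "TUP_IDN", ]
tidy(run$cues$TUP_IDN)
autoplot(run$strength)
render_report("results", reference = TRUE)
```
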