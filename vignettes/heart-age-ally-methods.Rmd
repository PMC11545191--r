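---
title: "Heart age, ALLY and atherogenic indices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart age, ALLY and atherogenic indices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartally)
```

## The heart-age score

The calculator maps six risk factors — total cholesterol, HDL-c,
fasting glucose, smoking, BMI and blood pressure — onto integer points
through sex-specific bands, adds the points to the chronological age
(CA), and reports the result as heart age (HA). ALLY, the avoidable
lost life years, is the signed difference HA − CA; we orient it so that
a negative ALLY means a heart younger than its owner, which makes the
population means come out negative for low-risk young women, as one
expects. High ALLY is declared at ALLY ≥ 17 years (inclusive: the
published cut-off names 17 itself without strictness, and we assign the
boundary to the riskier class, consistent with every other threshold in
the package).

The scale is defined for ages 18–80 and the package refuses ages
outside that window rather than extrapolating.

### Encoding the bands

The factor bands are shipped as a versioned JSON asset
(`inst/extdata/points_table_v1.json`), not code, so the mapping can be
audited and replaced wholesale. Printed bands such as `130–145 /
146–160` only cover integers; laboratory values are continuous, so each
ladder is normalized to half-open intervals on the reals — `[130, 146)`,
`[146, 161)`, … — which partition the positive half-line. A value can
therefore never fall between bands or into two at once
(`audit_points_table()` checks the encoding programmatically, along
with the point ranges, the per-sex minima sum of −20 and maxima sum of
+20, and that HDL-c is the only factor whose map differs by sex).

Two cells needed interpretation:

* The women's HDL-c ladder ends `71–75 → −4`, `<75 → −5` as printed;
  the final row would overlap the previous one, so it is encoded as
  `>75 → −5`, completing the ascending ladder exactly as the men's
  column does. We treat this as a typographical slip.
* Blood pressure bands are printed as joint labels (`120–139/80–89`)
  without defining discordant readings. We band systolic and diastolic
  pressure independently and take the band with the **higher points**,
  the convention of staged hypertension categories (a patient with SBP
  125 and DBP 95 is stage-2 by diastole, scoring +2).

Glucose and blood pressure carry a treatment override: treated
individuals score the factor maximum regardless of the measured value.
No analogous override exists for the lipid factors, matching the
original scale (which had no record of lipid-lowering therapy — a known
limitation inherited here).

### The asymmetric clamp

The factor minima sum to −20 and the maxima to +20, yet the scale's
definition caps the HA excess at +19. We clamp the total to
`[−20, +19]` as stated, and additionally report the raw unclamped sum
(`total_points`) so a user who prefers the symmetric reading can audit
either convention. The only profiles affected are those reaching the
full +20, i.e. maximal points on all six factors.

A structural consequence worth knowing: the five non-smoking factors
top out at +15, so **every** high-ALLY individual (≥ 17) is a smoker.
This is a property of the scale, not of our implementation.

## Atherogenic indices

The three indices are plain ratios of lipid fractions: TC/HDL-c,
LDL-c/HDL-c, TG/HDL-c. Categories: TC/HDL-c is low/moderate/high at
4.5 and 7 for women and 5 and 9 for men (boundaries inclusive in the
moderate class, as printed); LDL/HDL and TG/HDL are dichotomized at 3.
The TG/HDL rule is explicitly "elevated at 3 and above"; the LDL/HDL
prose ("low below 3, high above 3") leaves 3 itself unassigned, and we
resolve it as high for consistency with the TG rule.

LDL-c, when not measured, is derived by the Friedewald formula
LDL = TC − HDL − TG/5, reliable only for TG ≤ 400 mg/dL. Out-of-range
or negative results are reported but flagged invalid; such rows stay in
the cohort and are excluded **only** from LDL-based analyses (the
`ldl_hdl` index is NA there), maximizing the usable n per index.
Within each model fit, remaining missingness is handled complete-case;
because exclusion happens per analysis rather than per cohort, the two
conventions coincide except for rows missing a covariate entirely.

All analytes are fixed in mg/dL; no mmol/L conversion layer is
provided.

## The synthetic cohort generator

No individual-level data accompany the published study, so the
generator exists to make every downstream stage testable against known
truths. It emulates:

* the per-sex means/SDs of height, weight, waist, SBP, DBP, TC, HDL-c
  and glucose as truncated normals (exact inverse-CDF truncation at
  physiological bounds, e.g. HDL ≥ 10, SBP ∈ [80, 250]);
* triglycerides as a log-normal moment-matched to the printed mean/SD —
  the men's TG SD is almost equal to its mean, which no truncated
  normal can produce;
* the five-band age structure (uniform on a 0.1-year grid within each
  band) and the prevalences of smoking, physical activity,
  Mediterranean-diet adherence, alcohol consumption, social class and
  education.

Dependence among the metabolic fields is induced by a **single shared
standard-normal latent factor**: each loaded field is drawn as
`mean + λ·SD·Z + √(1−λ²)·SD·ε`, positively loaded on TC, TG (log
scale), glucose, weight and SBP and negatively on HDL-c. This keeps
every marginal mean and SD invariant in λ while giving pairwise
correlations of λ² between positively loaded fields, so calibration and
dependence can be reasoned about separately.

The default is λ = 0.7, giving metabolic correlations around 0.4–0.5 —
plausible for lipid/glucose/adiposity clustering. The choice matters
because high ALLY requires a smoker with near-maximal points on
essentially all metabolic factors: with independent fields the joint
probability is negligible and a cohort of tens of thousands contains
almost no cases. Even at λ = 0.7 the synthetic high-ALLY prevalence
(≈ 1% in men, ≈ 0.2% in women) is far below the real cohort's, because
one factor cannot reproduce the full dependence structure (age-varying
risk, smoker–metabolic correlation, treatment effects). The published
marginals say nothing about any of this, so we prefer one auditable
synthetic parameter over an invented covariance matrix.

What passing tests on this generator do show: the scoring, indexing,
ROC and regression machinery is correct against exact oracles and
recovers effects it is fed. What they do not show: that real screening
data have the simulated dependence, prevalence, or age gradients — the
generator has no age trend in its risk factors, so the published
pattern of indices rising with age is *not* emulated, and the
discrimination of the indices for high ALLY is higher in synthetic
cohorts (AUC ≈ 0.95–0.97) than in the real population (≈ 0.74–0.80).
Within this design the AUC also saturates in λ: more clustering creates
more cases but not more extreme ones, so we validate the monotone
effect of λ through the ALLY contrast between index categories, which
does grow with it.

For estimator validation, `inject_known_effect()` adds a simulated
binary outcome drawn from a logistic model with a stated log-odds
coefficient on a chosen covariate, giving the regression stage a known
truth to recover (mean OR and CI coverage are checked over 100
replicates at n = 5,000 in the test suite).

Weekly alcohol units for drinkers follow a log-normal with median 8 AU
(σ_log = 0.8), a synthetic shape chosen so that a realistic minority of
drinkers crosses the high-intake thresholds (≥ 14 AU for women, ≥ 21
for men, both inclusive — "consumes 14 AUs" reads as attained-at).
Mediterranean-diet scores are drawn uniformly from 9–14 for adherent
individuals and 0–8 otherwise, consistent with adherence defined as
score ≥ 9 of 14. Treatment prevalences default to zero (the original
scale's data carried no treatment records); they are configurable.

## Statistical stages

The ROC, logistic and goodness-of-fit stages are implemented in the
package (with `pROC` and `glm()` serving as independent cross-checks in
the test suite, never as the implementation):

* **ROC**: thresholds at the midpoints between consecutive distinct
  scores plus ±∞ sentinels, positive at `score ≥ threshold`; AUC by
  trapezoidal integration, which the tests verify equals the all-pairs
  rank statistic (concordant + ½ ties)/(n₁n₀) to 1e−12. The 95% CI uses
  the DeLong placement variance computed via midranks in O(n log n);
  a seeded stratified bootstrap (2,000 resamples) is available behind
  `ci_method = "bootstrap"`. The reported cut-off maximizes the Youden
  index J = sensitivity + specificity − 1, ties broken toward the
  smallest threshold; with constant scores the curve degenerates to the
  sentinels and J = 0 at −∞ by that rule.
* **Logistic regression**: IRLS (Newton) from a zero start, converged
  when the largest absolute score component < 1e−8, capped at 50
  iterations. Wald ORs and CIs, `exp(β ± 1.96·SE)`. Complete
  separation has no finite ML optimum; the gradient still vanishes as
  coefficients diverge, so the fit additionally flags any |β| > 30
  with an explicit separation warning, and a singular information
  matrix is an error, never a silent result.
* **Hosmer–Lemeshow**: deciles of predicted risk (default 10 groups),
  statistic Σ (O−E)²/(E(1−E/n_g)), df = groups − 2. Groups with
  degenerate expected counts merge into a neighbor with a message;
  if fewer than three groups remain (e.g. a saturated binary
  covariate, where the statistic is exactly 0), the statistic is
  reported without a p-value. Requesting ≤ 2 groups is an error.
  Calibration is validated by simulation: over 200 well-specified
  replicates the rejection rate at α = 0.05 must stay near nominal.
* **Stratified regression**: the same fit run independently within
  10-year age bands (20–69 by default), mirroring the published
  report's layout; the outcome is binary, so a two-level "multinomial"
  model is fitted as ordinary binary logistic. Strata that are empty
  or single-class are skipped with a warning.
* **Bivariate tables**: Welch t-tests for continuous fields; chi-square
  for categorical ones, with Fisher's exact test substituted (and
  recorded) whenever an expected cell is below 5. The significance
  convention throughout is 0.05.

## Problem sizes and reproducibility

Validation uses cohorts of 20,000 per sex for calibration and pattern
checks (1% mean-accuracy at that n), 100 replicates of n = 5,000 for
odds-ratio recovery, 200 replicates of n = 1,000 for goodness-of-fit
calibration, and 100 random datasets of n ≤ 500 against the exact AUC
oracle — sizes chosen to keep Monte-Carlo error well inside each
check's tolerance. All randomness descends from explicit integer
seeds: `generate_cohort(config, seed)` is bit-reproducible, and
`run_pipeline()` writes a manifest with the seed and an MD5 of every
output so identical inputs provably produce identical bundles.

## Known limitations

* The point bands, cut-offs and category thresholds reproduce the
  published scale exactly, but the original web calculator is defunct;
  behavior on inputs it may have handled specially (e.g. treated
  dyslipidemia) cannot be compared.
* The generator reproduces marginals, not the real joint distribution:
  absolute prevalences, AUCs and ORs from synthetic cohorts are not
  estimates of the published ones and are not meant to be.
* Whether the original analysis used inclusive or exclusive category
  boundaries, and whether the clamp ceiling was +19 or +20, is not
  recoverable; both package choices are documented above and the raw
  sum is always exposed.
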