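---
title: "Methods: risk-factor control, mortality and life expectancy in T2D"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk-factor control, mortality and life expectancy in T2D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package addresses

Adults with type 2 diabetes (T2D) die earlier than comparable adults without
diabetes, largely through cardiovascular disease (CVD). Diabetes guidelines
set explicit targets for six modifiable risk factors — three lifestyle
(never smoking, ≥ 150 min/week of physical activity, a healthy diet) and
three metabolic (HbA1c < 7.0 %, systolic blood pressure < 140 mmHg or
< 130 mmHg with prior CVD, and a joint lipid target of triglycerides
< 1.7 mmol/L with HDL-C ≥ 1.29/1.03 mmol/L for women/men). The analysis this
package implements asks how much of the mortality and life-expectancy gap
between people with T2D and matched non-diabetic controls is associated with
the number of those targets missed, and how much of any gain in life
expectancy is attributable to reduced CVD death.

The pipeline is: guideline-target scoring → propensity-score matching of T2D
cases to controls → Cox proportional-hazards estimation → abridged life
tables and life expectancy at age 50 with parametric-bootstrap CIs →
Arriaga age/cause decomposition → population-attributable fractions. Every
stage is exercised end-to-end on synthetic cohorts with known ground truth,
because the cohort data this style of analysis is run on (national
surveillance and biobank extracts) are access-restricted.

## Target scoring

`evaluate_targets()` judges each factor against a `threshold_dialect()`.
Boundary semantics follow the guideline wording exactly as printed: maxima
are strict (`HbA1c < 7.0` fails at exactly 7.0) and minima inclusive
(`HDL-C ≥ 1.03` passes at exactly 1.03). The lipid target is joint (TG and
HDL-C must both qualify), and the blood-pressure cut drops to 130 mmHg for
participants with CVD history. The unweighted score S counts factors
*outside* target (0–6), stratified as optimal (0–1), suboptimal (2–4), poor
(5–6).

Three diet-rule dialects are shipped, named for the cohorts whose designs
they emulate: an absolute fruit-and-vegetable/red-meat rule (CCDRFS), a
top-third-of-cohort diet-quality rule (NHANES), and a count of food-item
recommendations met (UKB, ≥ 5 of a configurable list; the component
definitions are config, not code). Two details are deliberate design
decisions:

* **Quantiles.** The diet tertile and the weighted-score cut points use
  type-7 linear interpolation of order statistics — the most common default
  — declared so results reproduce bit-for-bit. The tertile is computed once
  over the pooled cohort (not within survey cycles; the source design is
  ambiguous on this and pooling is the simpler reading).
* **Weighted score.** `weighted_score()` replaces the one-point-per-factor
  count with each factor's mortality log-hazard (estimated on the same
  cohort). Cut points are the weighted-score quantiles at the cumulative
  proportions of participants with S ≤ 1 and S ≤ 4, so category sizes track
  the unweighted ones; ties at a cut go to the lower-risk category, which
  keeps weighted category sizes from exceeding the unweighted ones.

A sensitivity dialect supports individualized per-participant HbA1c limits
and an LDL-C-based lipid rule (< 2.6 mmol/L).

## Matching

`estimate_propensity()` fits a logistic regression of T2D status on the
matching covariates (cohort presets: age/sex/residence, age/sex/race/cycle,
or age/sex/race). `nearest_neighbor_match()` is greedy 1:`ratio`
nearest-neighbour matching without replacement: cases in descending
propensity order, distance on the linear-predictor (log-odds) scale — better
behaved in the tails than the probability scale — with an optional caliper
(default none) and seed-controlled resolution of exact-distance ties. Cases
keep partial matches when controls run short, mirroring the slight
under-achievement of intended ratios that greedy optimizers produce; a case
with no eligible control is dropped. The source analysis delegated these
details to a matching package's internal optimizer, so the greedy variant
here is a declared default, verified in tests against a brute-force oracle.
`balance_table()` reports standardized mean differences before/after.

## Survival modelling

`fit_cox()` wraps a partial-likelihood fit with **Efron tie handling**
(follow-up is continuous, ties are rare, Efron is the accurate default) on
the follow-up time scale with age adjusted as a covariate (an attained-age
time scale is a reasonable alternative, but the adjustment-list reading of
the source design puts age among the covariates). Under the package's
Gompertz generator this specification is exactly proportional hazards:
baseline age enters the log hazard linearly with slope `gompertz_b`, a fact
the tests exploit by checking the recovered age coefficient.
`schoenfeld_ph_test()` runs the scaled-Schoenfeld score test with the
identity time transform. CVD-mortality models are cause-specific hazards:
non-CVD deaths are censored (whether the source did this is unstated; it is
the standard choice and is noted here).

The population-attributable fraction uses the adjusted standard formula

$$\mathrm{PAF} = P_d \times \frac{HR_{adj} - 1}{HR_{adj}},$$

with $P_d$ the proportion of deaths exposed. Its CI substitutes the HR's CI
bounds into the same formula; the source reports PAF CIs without naming a
method, and bound substitution is the simplest reproducible choice.

## Life tables and life expectancy at 50

`build_life_table()` constructs a Chiang-style abridged table over 5-year
bands from age 50 with an open 100+ band (the construction details of the
source's supplement are not public, so the standard recipe is fixed here by
design): $q_x = n m_x/(1 + (n - a_x) m_x)$ with $a_x = n/2$, radix
$l_{50} = 100{,}000$, and the open band closed by $L_x = l_x/m_x$. When
rates are extreme enough that $q_x$ caps at 1 before the terminal band, the
extinct tail carries zero survivors and zero remaining expectancy.

Group-specific mortality is the control (reference) schedule multiplied by
the group's all-cause hazard ratio uniformly across ages — the published
results provide one age-adjusted HR per group, so age-varying HRs are out of
reach. Sex-specific schedules are used throughout (Gompertz level calibrated
so the matched-control $e_{50}$ is ≈ 28.5 y for men and ≈ 33.1 y for women,
matching the published control values, with log-slope 0.092/yr — a standard
adult-mortality value). `monte_carlo_ci()` propagates the HR's sampling
uncertainty by parametric bootstrap: 1000 draws of
$\beta^* \sim N(\hat\beta, \mathrm{se}^2)$, a rebuilt table per draw, and
empirical 2.5th/97.5th **percentile** bounds (percentile rather than
normal-theory intervals, matching the parametric-bootstrap description).

## Arriaga decomposition

`arriaga_age_contributions()` splits $\Delta e_{50}$ into additive band
contributions (direct + combined indirect/interaction; the classic
presentation does not separate the latter two and neither does the source).
The contract direction is worse → better group, so positive contributions
read as years gained. `cause_partition()` allocates each band's contribution
to CVD vs non-CVD proportionally to each cause's share of that band's
all-cause rate difference — the standard cause-of-death extension; the
source's exact supplement formula is not public and this is the conventional
choice. Conservation (contributions summing exactly to $\Delta e_{50}$) is
enforced by property tests at 1e-9 relative tolerance, including schedules
driven to extinction.

## The synthetic-cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes:

* **Mortality** is Gompertz in attained age
  ($h(a) = a_0 e^{b (a - 50)}$, defaults $a_0 = 0.0038$/yr at age 50,
  $b = 0.092$/yr, giving $e_{50} \approx 30$ y) under a proportional-hazards
  linear predictor; event times come from the analytic inverse of the
  integrated hazard. Censoring is an administrative horizon (default 9.4 y,
  the Chinese cohort's maximum follow-up) plus light exponential dropout
  (0.002/yr).
* **Risk factors** are drawn from an equicorrelated Gaussian copula (default
  latent correlation 0.2 — baseline tables show clustering of factors but no
  joint distribution is published, so a modest default is declared, with the
  correlation exposed as a knob). Default outside-target prevalences follow
  the Chinese cohort's baseline table (smoking 34.9 %, inactivity 19.3 %,
  unhealthy diet 72.7 %, elevated HbA1c 35.7 %, elevated BP 46.8 %,
  dyslipidemia 60.7 %). Measurements are then drawn on the intended side of
  each threshold, so scoring recovers the generating flags exactly.
* **Effects** act either factor-wise (`factor_log_hazards`, summed over
  outside-target factors) or category-wise (`category_log_hazards`), the
  latter matching designs where the truth is a hazard ratio per control
  category (e.g. 1.0 / 1.5 / 2.3 for optimal / suboptimal / poor).
* **Cause of death** is an independent Bernoulli draw with CVD probability
  given by `cvd_death_fraction_fn` of the participant's outside-target
  count — a deliberate simplification that lets tests target a chosen CVD
  share of *excess* deaths without modelling competing risks.
* A **truth ledger** records each participant's exact linear predictor and
  the generating parameters, enabling parameter-recovery tests.

What the generator does **not** emulate: survey design (weights, strata,
PSUs), informative censoring, measurement error in self-reported lifestyle,
time-varying risk factors, and genetic data. Passing tests therefore show
the pipeline recovers truth under its own assumptions, not that those
assumptions hold in any real cohort. The NHANES-style top-third diet rule
structurally forces a one-third within-target fraction whatever the
generator's diet prevalence, so recovery tests use the absolute-threshold
dialect.

## Numerical and degenerate-input choices

* Life-table rates must be positive and finite; a band mismatch or
  non-positive rate is an error, not a warning.
* `cohort_mortality_rates()` splits follow-up over attained-age bands; a
  band with exposure but no deaths borrows the nearest informative band's
  rates (cause rates come along so all-cause = CVD + non-CVD stays exact) —
  without this, empirical schedules from finite cohorts would be unusable at
  the oldest ages.
* Zero pooled SD in a balance covariate reports SMD 0 with a degenerate
  flag; zero all-cause rate difference in a band yields zero cause
  contributions.
* Cox fits refuse < 2 events, rank-deficient designs, and factor levels
  with subjects but no events (monotone likelihood), naming the offender.
* Missing covariates: continuous → cohort median; categorical → explicit
  `"missing"` level entering design matrices as its own dummy. Missingness
  at or above 5 % per variable warns (the emulated cohorts stay below it);
  exposures must be resolved before scoring.

## Problem sizes

The test suite and the acceptance script run simulations at sizes chosen to
keep the whole suite fast while leaving comfortable statistical margins:
category-HR recovery uses 20 replicates of 20,000 participants (7,000 T2D);
the cause-share recovery uses 4 replicates of 50,000 T2D participants with
baseline ages spanning 50–95 so every age band accrues exposure; bootstrap
coverage uses 100 meta-replicates of 300-draw intervals. The analysis
drivers under `analysis/` use a single 35,000-participant cohort.

## Known limitations

* Proportional scaling of a reference schedule by a single HR ignores
  age-varying effects; it is the only option consistent with one published
  HR per group.
* The greedy matcher is not optimal matching; with scarce controls the
  assignment depends on processing order (descending propensity, as
  declared).
* PAF assumes the adjusted HR is causal and transportable, as the formula
  requires.
* Percentile bootstrap intervals can undercover when the HR's sampling
  distribution is strongly skewed at small event counts.
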