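---
title: "Methods: survival and Markov cohort modelling of heart-failure outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survival and Markov cohort modelling of heart-failure outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfmarkov)
```

## The problem and the data model

Two treatment arms of heart-failure patients (integrative vs conventional
therapy) are followed at 6-month visits for 6–36 months after their index
hospitalization; entry is staggered, so late entrants contribute short
follow-up. At each visit the NYHA functional class (I–IV) is recorded, or a
composite cardiovascular event (CVE: heart-failure readmission, acute
coronary syndrome, stroke, cardiovascular death) terminates follow-up. Two
questions are addressed:

1. **Does the treatment modality change the CVE hazard?** — the survival
   pipeline.
2. **How will the functional-class mix of each arm evolve beyond the observed
   horizon?** — the Markov cohort model.

## Survival stage

Event time is the month of the first CVE record; CVE-free patients are
censored at their last visit. Events therefore sit on the 6-month grid. We
deliberately do **not** model interval censoring: the visit design assigns
events to the visit at which they were ascertained, and every estimator
downstream is interpreted on that grid.

* **Kaplan–Meier / RMST.** "Average survival time" is the restricted mean
  survival time over [0, max observed time]: under the heavy administrative
  censoring of a 36-month window the unrestricted mean is undefined. Median
  CIs come from inverting the (log-scale) survival-curve CIs.
* **Log-rank** compares the arms; it is exact-level only asymptotically, and
  the package's null-calibration test (400 seeded replicates, KS test)
  verifies the p-value is uniform under the null of its own generator.
* **Nested Cox tiers.** Tier I (age, gender), tier II (+ BMI, medications,
  comorbidities, smoking, admission NYHA as a factor), tier III (+ continuous
  labs, LVEF, LVMI, untransformed). Ties are handled with the Efron
  approximation: with at most six distinct event times, tie handling is the
  dominant numerical choice, and Efron is the accurate default at these tie
  fractions. The acceptance suite measures the residual grid-plus-Efron bias
  of the log hazard ratio directly (≈ +0.01 at a true HR of 0.322, against a
  bound of 0.05). A shortfall below 10 events per covariate warns but does
  not stop the fit. Separation and constant-arm designs raise errors;
  constant covariates inside subgroups are dropped with a message.
* **Discrimination.** Harrell's C on the fitted risk score, and a
  cumulative/dynamic time-dependent ROC at 12 months with
  inverse-probability-of-censoring weights from the Kaplan–Meier estimate of
  the censoring distribution (evaluated left-continuously). Both are
  invariant under strictly monotone transforms of the risk score, and the
  test suite asserts this property rather than any numeric AUC.

## Markov stage

Five states: NYHA I–IV and absorbing CVE. The 6-month transition matrix is
estimated by maximum likelihood from paired discharge → 6-month states:
`P[i, j] = n[i, j] / n[i]`. Choices a maintainer should know:

* **Time homogeneity.** The matrix is fixed from the 0→6-month window and
  applied for all 10 cycles (60 months). This is the model's central
  simplifying assumption; a time-varying hazard (the "acute vulnerable
  period" is real — see the generator) makes the fixed matrix an early-window
  snapshot, which tends to overstate long-horizon CVE. The 12-month
  goodness-of-fit test is the guard rail the design provides.
* **Zero rows.** A source state never observed gets self-transition
  probability 1 ("inert", with a warning) rather than invented mass;
  a "uniform" policy is available by argument.
* **Initial distribution** is the discharge-state mix of patients alive at
  discharge; in-hospital deaths are excluded from the Markov baseline (they
  never enter follow-up).
* **Cycle mapping.** Year y = cycle 2y; no half-cycle correction, matching
  plain state counting at visits. `predict_at_years()` refuses non-integer
  cycles rather than interpolating.
* **Reporting.** Percentages are rounded half-up to one decimal; internal
  math is full precision.
* **Validation.** `gof_test()` compares predicted cycle-2 shares with the
  observed 12-month distribution among *determinate* patients: a visit at
  month 12, or a prior CVE carried forward; patients censored earlier leave
  the denominator. This denominator convention is why Markov CVE shares
  exceed Kaplan–Meier cumulative incidence at the same month. Categories
  with predicted probability 0 and observations present are an error
  (advising a merge); expected cells below 5 warn by default rather than
  auto-merging.
* **Arm comparison** converts the two predicted distributions to counts
  (`round(n·p)`) and applies a chi-square homogeneity test on the 2×k table,
  dropping empty columns; no continuity correction.

## The synthetic world

The generator emulates a 394-patient two-arm cohort (181/213) whose
covariates match published baseline tables: normal variables by mean/SD,
skewed labs (creatinine, Hs-CRP, NT-proBNP) by log-normals matched to
median/quartiles, flags by proportions, admission NYHA by the printed
class counts. Specific choices:

* **Age** is truncated to the inclusion window [18, 75]. The printed mean/SD
  are used as the *untruncated* parameters, so the realized mean is lower by
  construction; recovery tests compare against the analytic truncated mean
  (`truncnorm_mean()`).
* **Echo dimensions** are back-solved from a target LVMI draw (wall
  thicknesses solved from the Devereux identity given a plausible LVIDd), so
  stored LVM/BSA/LVMI always satisfy their defining formulas exactly — an
  invariant the validator re-checks at 1e-9.
* **Floors** (weight ≥ 35 kg, TG ≥ 0.2 mmol/L, hospital days ≥ 0, etc.)
  prevent physiologically impossible draws at the cost of a negligible shift
  in moments; hospital days are integers.
* **Entry** is uniform over a 30-month window, giving 6–36 months of
  potential follow-up on the 6-month grid; the 6-month visit is guaranteed
  (minimum follow-up by design). **Dropout** is exponential at 10%/year — a
  parameter, not a claim of fidelity, since no dropout rate is published.
* **Discharge distribution** per arm (I 5/4%, II 32/33%, III 43/47%,
  IV 20/16%) encodes modest in-hospital improvement from the printed
  admission mix; it is a design choice, stated once here.
* **Default transition matrices** were chosen so that two cycles give
  roughly the published 1-year CVE shares (≈42% integrative, ≈54%
  conventional) from the default discharge mixes, with plausible
  improvement/deterioration structure elsewhere. They are a stated world for
  testing, not estimates.
* **Two CVE mechanisms.** `mode = "matrix"` (default) produces CVE only
  through the transition matrices — the world the Markov estimator assumes.
  `mode = "hazard"` draws a latent continuous event time from a
  piecewise-exponential proportional-hazards clock (baseline 0.081/month for
  months 0–6, 0.027/month after — a 3× "acute vulnerable period", magnitudes
  being config defaults; integrative hazard multiplied by `true_hr = 0.322`)
  and overrides the trajectory's CVE channel. This mode exists so the
  survival stage can be tested against a known hazard ratio; the two modes
  are mutually exclusive. In hazard mode NYHA dynamics use the transition
  matrix renormalised over the non-CVE columns.
* **In-hospital deaths** (default rate 2/181 in the integrative arm, 0
  conventional) are emitted with discharge code 0 and no follow-up, and are
  excluded from both the survival dataset and the Markov baseline.
* **Reproducibility.** All randomness flows from one seed through fixed
  per-stage substreams (covariates, entry, censoring, trajectories, hazard),
  so the same seed reproduces the cohort byte-for-byte and stages can be
  varied independently.

**What a green test establishes — and what it does not.** The generator
draws covariates independently within arm (no correlation structure, no
confounding by indication beyond the arm-specific marginals), uses exactly
proportional hazards, exact visit compliance, and memoryless dropout. Green
parameter-recovery and calibration tests therefore establish that the
estimators are correct *under their own assumptions*; they say nothing about
robustness to informative censoring, covariate-dependent hazards, or visit
irregularity, none of which the stated world contains.

## Numerical and degenerate-input policy

Transition matrices must be row-stochastic to 1e-12 with CVE absorbing;
cycled distributions are checked to sum to 1 within 1e-9 and iterative
cycling agrees with an independent matrix-power oracle to 1e-12. Chi-square
tests use no continuity correction (including 2×2). Two-sided p-values
throughout. Kruskal–Wallis is used as the named rank test for two groups
(equivalent to Mann–Whitney up to the χ² formulation). Baseline rows with
fewer than 2 observations per arm are flagged untestable, never silently
dropped. Missing lab values are handled variable-wise (complete case per
table row); no imputation anywhere. Categorization bins are half-open
[low, cut) / [cut, high): a value exactly at a cut-point falls in the upper
bin. The default categorization thresholds are reference-range placeholders
chosen by this package (the original study's supplementary cut-points are
not public) and should be overridden for any serious reanalysis.

## Known limitations

* Time-homogeneous transition probabilities (see above); no time-dependent
  Markov extension.
* No competing-risks decomposition of the CVE composite.
* No interval-censoring model; event times are visit-grid resolutions.
* Proportional-hazards diagnostics are limited to what `survival` provides;
  the package does not gate fits on a Schoenfeld test.
* Published patient-level results (adjusted HR 0.322, medians 21 vs 14
  months, C = 0.701, AUC = 0.697, log-rank χ² = 12.58) are provenance
  anchors: they cannot be recomputed without the confidential cohort, and
  nothing in this package claims to reproduce them. The worked example in the
  README shows what the pipeline prints on its own synthetic world.
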