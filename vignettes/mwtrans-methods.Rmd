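---
title: "Methods: the six-state metabolism-weight transition model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the six-state metabolism-weight transition model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwtrans)
```

## The phenotypes and their definitions

Six mutually exclusive metabolism-weight phenotypes are cross-defined from
weight category and metabolic status, indexed 1-6 in the fixed order MHNW,
MHOW, MHO, MUNW, MUOW, MUO everywhere in the package.

Weight uses the Chinese adult BMI cut-offs with closed lower bounds: normal
weight 18.5 <= BMI < 24 kg/m², overweight 24 <= BMI < 28, obesity BMI >= 28.
BMI below 18.5 is not a category but an eligibility exclusion, so
`classify_weight()` refuses it rather than inventing an underweight level.

Metabolic status counts four revised NCEP ATP III criteria (abdominal
obesity deliberately omitted - waist circumference is typically absent from
check-up records): elevated blood pressure (SBP >= 130 or DBP >= 85 mmHg, or
antihypertensive medication), elevated glucose (FPG >= 5.6 or 2-h post-load
glucose >= 7.8 mmol/L, or hypoglycemic medication), triglycerides >= 1.7
mmol/L, and low HDL-C (< 1.0 male, < 1.3 mmol/L female). Two or more
criteria make a record metabolically unhealthy. The inequality sides follow
the printed definitions: `>=` for pressure, glucose and triglycerides,
strict `<` for HDL. A missing 2-h glucose contributes false to the glucose
criterion rather than invalidating the record, because routine check-up
panels rarely include an OGTT; `require_pg2h = TRUE` restores the strict
reading. Units are fixed (mmol/L, mmHg, U/L, umol/L); `read_checkups()` can
declare mg/dL glucose/lipid inputs and converts once on load, never
silently.

The model covariates are six baseline-reference binaries: `female`,
`middle_aged` (age > 45, the usual perimenopause boundary), and elevated
ALT (> 40 U/L), AST (> 40 U/L), SCr (> 133 male / > 106 female umol/L), UA
(> 420 male / > 360 female umol/L). "Elevated" is strict: a value exactly at
a threshold belongs to the normal group.

## Transition structure

Instantaneous transitions are permitted only between adjacent phenotypes:
one step of weight within a metabolic row, or a metabolic flip within a
weight column. On the 2x3 grid this gives 14 directed edges; diagonal or
weight-skipping moves (MHNW to MUOW, MHNW to MHO) are structurally zero in
the generator. They still occur in the data over a year's gap - the model
explains them as two or more latent jumps, and `P(t) = exp(Qt)` gives them
positive probability for any `t > 0`. There is no absorbing state: every
state has positive exit intensity in any realistic fit, and the machinery
flags an infinite sojourn explicitly if one arises.

## Likelihood and estimation

States are observed only at visits (panel observation), so each consecutive
pair contributes `P_z(t_{k+1} - t_k)[s_k, s_{k+1}]`, with the generator
adjusted by the covariates at the interval's *start*
(`q_rs(z) = q_rs(0) exp(beta_rs' z)`); covariates are therefore
stepwise-constant between visits, and a subject crossing age 45 during
follow-up switches groups from the next interval on. The log-likelihood
sums these terms over subjects. Implementation notes:

* Intervals sharing (length, covariate pattern) reuse one matrix
  exponential, and repeated (from, to) cells within such a group collapse
  to counts, so an evaluation costs one `exp(Qt)` per distinct group.
  Interval lengths are keyed at 12 significant digits.
* The matrix exponential is scaling-and-squaring with Pade approximants
  (order chosen by the 1-norm, as in the standard algorithm). Tests verify
  it against a truncated-Taylor oracle and `Matrix::expm` to 1e-8 and the
  Chapman-Kolmogorov identity to 1e-8; rows of `P(t)` sum to 1 within
  1e-10.
* A parameter point whose rates overflow, or whose exponential degenerates
  numerically (entries outside [0, 1]), is rejected as `-Inf` rather than
  letting `log P > 0` masquerade as likelihood.

Maximisation starts from crude rates - observed moves per edge divided by
person-time in the origin state (attributing each interval to its starting
state), floored at 1e-3/year for unobserved edges - runs BFGS with
central-difference gradients to a relative tolerance of 1e-8, then applies
up to ten Newton steps on the central-difference observed information
(step `1e-5 * max(1, |theta|)`), stopping when the gradient norm falls
below 1e-4. The `converged` flag reports exactly that criterion. The
covariance matrix is the inverse observed information; a singular
information matrix leaves `vcov` absent (point estimates are still
returned) and the Newton polish falls back to a ridged solve so identified
parameters still converge.

Parameters live on unconstrained scales (log intensities, raw beta).
Confidence intervals are normal approximations on the log scale, hence
asymmetric on the natural scale: intensities `exp(log q +- 1.96 se)`,
hazard ratios `exp(beta +- 1.96 se)`, and sojourn times by the delta method
on the log total exit rate. The default covariate model is one joint
multivariable fit with every covariate on all 14 edges;
`fit_mwm_univariable()` provides the per-covariate alternative since
published analyses do not always state which was used.

## Descriptive tabulations

`tabulate_transitions()` pools *all* consecutive visit pairs, not only
pairs almost exactly a year apart - with a mean inter-visit gap near one
year the pooled reading is the natural interpretation of an "about 1 year"
transition-frequency table, and it uses every observation. Percentages are
row-normalised and rounded half-up to two decimals, matching how printed
tables round. Eligibility exclusions (baseline BMI < 18.5, baseline age
outside 20-60, disease history at any visit, missing baseline fields,
fewer than two visits) are applied in that order so each excluded subject
carries exactly one primary reason.

The package bundles the reference cohort's published tabulations
(`reference_transition_counts()`, `reference_baseline_counts()`,
`reference_sojourn_times()`) and minimal panel reconstructions that
reproduce every printed percentage exactly; the raw records behind them are
not publicly deposited, which is precisely why the simulator below exists.

## The cohort simulator

`simulate_cohort()` is an exact event-driven simulator: exponential holding
times with rate `-q_rr`, categorical destinations `q_rs / -q_rr`, truncated
at the horizon. Latent paths are kept alongside the observed panel so
oracle checks can compare visit-to-visit frequencies against `exp(Q dt)`
without discretisation bias.

Defaults are fixed to emulate the reference cohort:

* baseline phenotype mix = the published baseline proportions
  (0.4503 / 0.1808 / 0.0360 / 0.0942 / 0.1593 / 0.0793);
* the six metabolic-edge intensities are the published values
  (deterioration 0.15, 0.38, 0.56; improvement 0.64, 0.44, 0.27). The
  published summary names the 0.44 improvement inconsistently with the
  adjacency structure (a diagonal move); this package attaches it to the
  adjacent MUOW-MHOW edge, the only reading compatible with the 14-edge
  structure;
* the eight weight-edge intensities are *derived, not published*: each
  state's total exit rate is pinned to the reciprocal of its published mean
  sojourn time (3.84, 1.56, 1.16, 1.23, 1.59, 2.34 years), and where a
  state has two weight edges the remaining exit mass is split in
  proportion to the published observed transition counts;
* covariate prevalences: female 0.5227 and middle-aged 0.253 as published;
  the elevated-marker prevalences (ALT 0.10, AST 0.03, SCr 0.01, UA 0.15)
  are unpublished and set to values typical of adult check-up populations;
* visits: counts 2-8 with mean about 3.7 (matching the reference ratio of
  25,985 transitions to 9,742 subjects), intervals of 12 months plus
  rounded normal jitter (sd 1 month) clamped to 9-15 months, follow-up
  capped at 8 years. Month-granular jitter mirrors how check-ups are
  actually scheduled and keeps the set of distinct interval lengths small,
  which the grouped likelihood exploits;
* covariates are drawn once at baseline and held fixed, keeping recovery
  tests interpretable; age still advances in the emitted measurements, so
  re-dichotomisation can realistically flip `middle_aged` mid-follow-up.

`emit_measurements()` converts latent states to raw records by
construction, not rejection: BMI is drawn inside the latent weight
category's interval (normal-weight centred at 21.6 kg/m², near the
reference MHNW median), the visit's drawn set of metabolic criteria
(2-4 when unhealthy, 0-1 when healthy) is realised by sampling each
measurement strictly on its side of the defining threshold, and a small
fraction of satisfied pressure/glucose criteria are carried by medication
flags with normal measurements. Re-classification therefore reproduces the
latent states exactly, which the tests assert for multiple seeds.

What the simulator does *not* emulate: the joint distribution of the
biochemistry beyond threshold consistency and the BMI anchor, within-person
autocorrelation of measurements, informative dropout, secular trends, or
state dynamics beyond a time-homogeneous Markov chain. Passing recovery
tests therefore demonstrates that the estimator inverts the model it
assumes - not that real cohorts satisfy that model; the
observed-vs-expected prevalence check is the tool for the latter question.

## Goodness of fit

`prevalence_series()` compares, on a yearly grid 0-7 by default, the
observed state mix (each subject under observation contributes its most
recent state, last observation carried forward) with the model-expected mix
(averaging each under-observation subject's `P_z(t)` row from its baseline
state and covariates). Restricting the denominator to subjects still under
observation mirrors the declining cohort size of real check-up data, where
only a minority accumulate four or more visits. The published convention
for this plot's denominator is not stated; the carried-forward /
under-observation convention is this package's documented choice. The
summary statistic is the largest absolute per-state gap in percentage
points - the published assessment is visual, and no formal panel-data GOF
test is attempted.

## Problem sizes and numerical conventions in the test suite

The suite validates recovery at 2,000 subjects with six exactly annual
visits (reading "annual visits" literally for that fixture), covariate
recovery at 4,000 subjects with a doubled female MHOW-to-MHNW rate, and
interval calibration with 20 null replicates of 1,000 subjects; oracle
comparisons use up to 100 random generators. These sizes are the package's
choice of a thorough-but-routine regression suite; the acceptance script
refits at the full reference scale of 9,742 subjects.

One calibration fact the suite itself computes deserves note: with a few
thousand subjects, the weakly travelled weight edges (true rates of order
0.05-0.17/year) carry per-edge relative sampling errors of roughly 10-16%,
so simultaneous tight recovery of *all* 14 intensities is only reliable at
study scale. The likelihood and optimiser are validated independently of
sampling noise by closed-form two-state oracles and a grid-search MLE
comparison at 1e-4.

## Limitations

Time-homogeneous intensities (no age- or calendar-time-varying baseline
rates); no misclassification/hidden-Markov layer over the observed states;
no semi-Markov sojourn distributions; no imputation of missing
measurements; and hazard ratios assume proportional intensities per edge.
These mirror the modelling assumptions of the analysis the package
implements, and extending any of them is out of scope.
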