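---
title: "Projecting post-conflict mental health burden and service needs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting post-conflict mental health burden and service needs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conflictmh)
```

## The problem

Armed conflict raises the prevalence of post-traumatic stress disorder
(PTSD) and major depression in exposed populations, and health planners in
low- and middle-income countries need burden and staffing estimates long
before local epidemiological surveys exist. `conflictmh` implements a
projection chain that answers that need from already-published evidence:

1. **Stratified prevalence.** A random-effects meta-regression of
   study-level prevalence surveys from conflict-affected populations,
   with prevalence predicted for strata defined by political terror and
   trauma exposure.
2. **Severe cases.** Total prevalence is reduced to the severely impaired
   subgroup using severity proportions pooled from the World Mental Health
   Surveys.
3. **Case projection.** Severe-case prevalence is applied to chosen
   population groups, with explicit rounding conventions.
4. **Comorbidity.** Cases are split into depression-only, PTSD-only and
   comorbid planning groups.
5. **Services and workforce.** Coverage targets give patients per service;
   a staffing algorithm converts caseloads to full-time-equivalent (FTE)
   clinicians; WHO per-100,000 availability rates give the workforce gap.

## The meta-regression model

Each survey \(i\) reports \(c_i\) cases among \(n_i\) respondents. The
observed prevalence is transformed to a logit,
\(y_i = \mathrm{logit}(c_i/n_i)\), with delta-method within-study variance

\[ v_i = \frac{1}{c_i} + \frac{1}{n_i - c_i}. \]

The working model is the standard normal–normal random-effects
meta-regression

\[ y_i \sim N(x_i^\top \beta,\; v_i + \tau^2), \]

where \(x_i\) contains an intercept plus study-level covariates
(methodological: measure type, sampling; substantive: political terror,
trauma exposure, time since conflict, displacement) and \(\tau^2\) is the
between-study variance. Stratum prevalences are back-transformed from the
linear predictor, \(\hat p = \mathrm{expit}(x_0^\top\hat\beta)\), with a
Wald interval on the logit scale; odds ratios are exponentiated contrasts
between a stratum and the reference profile.

### Covariates and strata

Two standardised exposure measures drive the substantive stratification:

* **Political Terror Scale (PTS)**, a 1–5 country-year rating of state
  violence; ratings of 4–5 define *high political terror*.
* **PTE adversity ratio**, the mean number of potentially traumatic events
  endorsed by a sample divided by the number assessed by its instrument.
  The ratio standardises exposure across trauma checklists of different
  lengths; values \(\ge 0.3\) define *high trauma*.

Both cut-offs are configurable in `stratify_exposure()` but default to the
thresholds above, which correspond to the elevated-risk thresholds
identified in the source meta-regression.

### Estimation

Two estimators of \(\tau^2\) are implemented in `fit_prevalence_model()`:

* **REML** (default): the restricted log-likelihood is profiled over
  \(\tau^2 \ge 0\) by golden-section search to a tolerance of `1e-8`, with
  the boundary checked explicitly so homogeneous data return exactly
  \(\hat\tau^2 = 0\). Weighted least squares at the optimum gives
  \(\hat\beta\) and its covariance \((X^\top W X)^{-1}\),
  \(W = \mathrm{diag}\{1/(v_i+\hat\tau^2)\}\).
* **Moment**: the extended DerSimonian–Laird estimator,
  \(\hat\tau^2 = \max\{0, (Q_E - (k-p))/\mathrm{tr}(P)\}\) with
  \(P = W_0 - W_0X(X^\top W_0X)^{-1}X^\top W_0\) and \(W_0\) the
  fixed-effect weights, followed by weighted least squares. With an
  intercept-only design this reduces exactly to the classic
  DerSimonian–Laird pool, which is what `pool_proportions()` uses for
  severity proportions.

REML is the default because the published analysis used a mixed-model fit
in a commercial package without stating the variance estimator; REML is the
common default in that setting, and the moment estimator is retained as a
closed-form cross-check (the two agree closely on well-behaved data).

### Numerical choices

* **Boundary counts.** Surveys with \(c_i = 0\) or \(c_i = n_i\) have an
  undefined logit; 0.5 is added to the cases and 1.0 to the sample before
  transformation. The generator deliberately retains such surveys so the
  correction path is exercised.
* **Intervals.** All 95% intervals are Wald intervals with \(z = 1.96\)
  (the conventional figure at which published symmetric logit intervals
  back-calculate); other confidence levels use the exact normal quantile.
  No small-sample (Knapp–Hartung) adjustment is applied by default.
* **Stratum CIs, not prediction intervals.** `predict_stratum()` excludes
  \(\tau^2\) from the standard error: the interval quantifies uncertainty
  in the stratum *mean* prevalence, matching the role of the narrow
  published intervals, not the spread of a hypothetical new survey.
* **Rank deficiency** in the design matrix is an error naming the
  collinear columns, not a silent drop.
* **Heterogeneity decomposition.** `variance_explained()` reports
  \((\tau^2_{null}-\tau^2_{base})/\tau^2_{null}\) for a baseline
  methodological block and
  \((\tau^2_{base}-\tau^2_{full})/\tau^2_{null}\) for the additional
  substantive share, each floored at zero; a zero null \(\tau^2\) returns
  zero with a warning.

## The synthetic study-table generator

The original 117-survey table is not available in machine-readable form, so
`generate_study_table()` emulates the model's assumed data-generating
process: covariates are drawn from distributions spanning the
stratification thresholds (sample sizes uniform on 50–1000, PTS uniform on
{2,…,5}, PTE adversity ratio uniform on 0.05–0.6, years since conflict
uniform on 0–10, binary covariates Bernoulli(0.5)); the true logit is
\(x_i^\top\beta + u_i\) with \(u_i \sim N(0,\tau^2)\); and counts are
binomial. The true logit and probability are recorded per study so recovery
experiments have an oracle.

What the generator does *not* emulate: correlated covariates (real
methodological and substantive factors co-vary), instrument-specific
measurement error, publication bias, or clustering of surveys within
countries. Passing recovery and coverage tests therefore demonstrates that
the estimation machinery is correct under the model's own assumptions —
not that the model is correct for real survey collections.

Simulation scale: recovery experiments use 200 surveys per table with 200
replicate fits, and the interval-coverage experiment uses 500 replicates;
at these sizes the coefficient and \(\tau^2\) Monte-Carlo standard errors
are small enough to detect biases of a few percent while the whole
experiment remains a desk-scale computation (seconds).

## Severity, comorbidity and case projection

Severity proportions come from Sheehan Disability Scale (SDS) ratings of
30-day cases: scores 0–3 mild, 4–6 moderate, 7–10 severe
(`categorize_sds()`). The shipped constants — 30.0% (27.0–33.0) of PTSD
cases severe, 53.0% (46.0–60.0) of depression cases — are pooled
random-effects proportions from the World Mental Health Surveys, with
anxiety disorders standing in for PTSD and affective disorders for
depression; `pool_proportions()` implements the pooling operation
generically for any severity table.

`severe_prevalence()` multiplies the total prevalence *and both interval
bounds* by the point severity proportion. The severity estimate's own
uncertainty is intentionally not propagated: published severe-case
intervals are exactly the total intervals scaled by the point proportion,
and the package mirrors that convention so its tables are comparable.
`severe_prevalence_mc()` offers Monte-Carlo propagation (logit-normal
draws for both quantities) as a sensitivity analysis; it widens the
interval, as expected.

Case projection multiplies group size by severe prevalence and rounds
half-up to the nearest 100 (the planning-table convention; `4,950 → 5,000`,
and the 216.5-patient service cell rounding to 217 confirms half-up rather
than banker's rounding). Totals are sums of the already-rounded group
values. In reproduction mode the one-decimal percent values are used, which
is exactly consistent with the acute-phase planning table; `rounding_unit =
1` with full-precision prevalences serves model-driven work. The
medium-term (three-year) projection table evidently used unrounded
prevalences and is internally inconsistent at the hundreds digit, so only
the acute-phase table is treated as an exact reproduction target.

Comorbidity: 50% of severe PTSD cases are taken to be comorbid with severe
depression (`phi`, configurable). `comorbidity_split()` computes
`comorbid = round(phi × PTSD)`, `ptsd_only = PTSD − comorbid`, and
`depression_only = depression − comorbid` by subtraction. The published
planning figures instead pair 61,600 comorbid and 61,600 PTSD-only cases
with a 43,300 depression-only group, which is not the subtraction result
(228,100 − 61,600 = 166,500) and is not derivable from the other published
numbers; reproduction mode therefore injects the published 43,300 as an
explicit override, and model-driven mode uses subtraction.

## The service and staffing model

Coverage targets (fraction of a planning group using a service over one
year) ship as published for severe depression — long-stay 0.5%, acute
inpatient 2%, day care 1%, outpatient 20%, primary care 30%, psychosocial
20% — extended to comorbid (1/4/1/20/40/20%) and PTSD-only cases (primary
care 10%, psychosocial 20%, nothing else, reflecting guidance that
non-comorbid PTSD is managed in primary care and psychosocial settings).
Patients per service are `round_half_up(group × coverage)`.

Ambulatory staffing uses the published algorithm

\[ \mathrm{FTE} = \frac{\text{population} \times \%\text{prevalence} \times
\%\text{severity} \times \%\text{coverage} \times \text{visits per case}}
{11 \text{ consultations/day} \times 225 \text{ working days}}, \]

where visits per case is the service-use fraction times the average use of
a service user (e.g. 1% day-care use × 50 visits = 0.5 visits per average
case). Because the numerator factors are algebraically interchangeable, the
package exposes both entry points: `fte_ambulatory()` (the full product)
and `fte_from_visits()` (patient counts × average visits). Inpatient FTE is
staff:bed ratio × targeted beds (`fte_inpatient()`), with beds derived from
patients × bed-days/365 in the pipeline. Service FTE is apportioned across
medical, nurse and psychosocial categories by a row-stochastic matrix and
rounded half-up per category (`apportion_staff()`).

The per-service visit rates, bed-day targets, staff:bed ratios and the
apportionment matrix are **not published** with the coverage targets (they
derive from an external costing model); the shipped values are documented
placeholders chosen within the ranges used by LMIC mental-health costing
studies. Consequently the staffing tables the pipeline prints are
reference output of the algorithm under the placeholder configuration, in
the same order of magnitude as the published 154-FTE requirement but not a
reproduction of it; the published FTE density (12.5 per 100,000) is
computed from the published 154-FTE total as a given input.

Workforce availability applies WHO per-100,000 rates — 0.18
psychiatrists/psychiatric medical officers, 0.5 psychiatric nurses, 6.5
psychosocial providers — to the combined population
(`workforce_gap()`); shortfall is `max(0, required − available)`.

## Pipeline modes and reproducibility

`run_pipeline()` has two explicit modes, never inferred:

* `paper_reproduction`: injects the published stratum prevalences
  (shipped in `inst/extdata/stratum_estimates.json`), the one-decimal
  percent convention, and the published depression-only override — the
  configuration that reproduces the published planning tables without the
  original survey dataset.
* `model_driven`: fits the meta-regression to a supplied or simulated
  study table, predicts strata at full precision, and derives all groups
  arithmetically.

Every stochastic operation takes a seed and restores the caller's RNG
state; a run with the same configuration writes byte-identical outputs,
and each report carries a provenance block (package and R versions, mode,
seed, MD5 of the serialised configuration). Stage failures propagate with
the stage name attached.

## Known limitations

* The generator's covariate independence means simulation results bound
  estimation error only under idealised conditions; confounded real-world
  covariate structures can inflate the variance of stratum contrasts.
* Published odds ratios and variance-explained percentages from the
  original 117-survey analysis cannot be reproduced without that dataset;
  they guide the magnitudes used in recovery experiments only.
* The published acute-phase PTSD total's upper uncertainty bound is not
  consistent with the sum of its own per-group bounds; the package reports
  the sum-of-rounded value its stated convention produces.
* Torture prevalence, a known risk factor, is not modelled (insufficient
  source information), and national-level extrapolation is out of scope.
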