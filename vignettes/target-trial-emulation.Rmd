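---
title: "Sequential target-trial emulation for claims data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential target-trial emulation for claims data: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`seqtte` implements the analysis pipeline used to estimate the association of
a universal annual health checkup (Japan's Specific Health Checkup, SHC) with
incident type 2 diabetes and hypertension from employee-insurance claims
data, organized as an emulation of a sequence of nested randomized trials.
This vignette explains the statistical machinery, the synthetic claims
generator that stands in for the proprietary source data, and the design
decisions that were genuinely open.

## The emulated trial

Each Japanese fiscal year (April 1 through March 31) defines one emulated
trial. At the fiscal-year start, every insured person is screened against
the eligibility criteria: age 40-74 in completed years, at least
`lookback_days = 365` days of continuous enrollment, at least one medical
visit in that lookback window, no checkup anywhere in the observable
history, no prevalent diabetes (ICD-10 E10/E14 plus a glucose-lowering A10
dispensing) or hypertension (I10-I15 plus an antihypertensive C02/C03/
C07-C09 dispensing), and resource use at or below the 99.99th percentile of
the screened population (a proxy for institutionalized individuals).
Eligible persons who have a checkup record inside that fiscal year form the
SHC arm of that trial; the rest form the non-SHC arm. A person can enter
the non-SHC arm of many successive trials but the SHC arm only once, in the
year of their first checkup.

Time zero is April 1 of the trial year for both arms, even though the
checkup itself happens later in the year: a single, common time origin per
trial is what removes immortal-time bias, and the within-year timing of
checkups is not informative in these data. The contrast is intention-to-
treat: non-SHC entrants who take a checkup later are neither censored nor
re-classified.

The outcome is the earliest date at which a qualifying diagnosis code is
recorded with a matching medication dispensed within
`conjunction_window_days = 90` days (the code-plus-medication rule needs
*some* pairing window; 90 days is a conventional claims-linkage choice and
it is configurable). The composite outcome is the earliest of its diabetes
(E11/E14 + A10) and hypertension (I10-I13, I15 + C02/C03/C07-C09)
components, each paired with its own drug class. Two coding quirks are
exposed as options rather than silently corrected: the fifth hypertension
code is I15 by default (`hypertension_extra = "E15"` reproduces the
alternative printed coding, which designates a hypoglycaemia code and is
almost certainly a transposition), and the negative-control depression set
is F32/F34/F35 as printed even though F35 is not an assigned ICD-10
category (configurable).

## Estimation

Follow-up is discretized into at most ten one-year intervals (monthly
intervals are available for the monthly-entry sensitivity design). Entry
`i`, interval `k` contributes one person-period row with an event indicator,
and the discrete-time hazard is modelled by weighted pooled logistic
regression:

```
logit P(event in k | at risk) = b0 + bA * A + s(k) + g_fy
```

where `A` is assignment, `s(k)` a restricted cubic (natural) spline of
interval index with four knots at the 5/35/65/95 percent quantiles of the
observed interval distribution, and `g_fy` trial-year main effects (below).
`exp(bA)` is the discrete-time hazard (odds) ratio — the standard
hazard-ratio approximation when per-interval risks are small, as they are
here (about 2% per year). Because the design matrix depends only on
`(A, k, year)`, person-periods are aggregated to design cells before
fitting, so the fit costs the same at 10^3 or 10^7 rows.

Confounding is adjusted by stabilized inverse-probability-of-treatment
weights `sw = P(A = a | year) / P(A = a | L)`. The denominator comes from
one pooled maximum-likelihood logistic propensity model across all trials
(entry year as a covariate) on: age at entry, sex, entry year, employment,
hospitalization count in the prior year (0 / 1 / 2+), visit count in the
prior year (1-2 / 3-5 / 6-11 / 12+), and a binary indicator for every
3-digit ICD-10 family recorded before entry, after dropping indicators with
cohort prevalence below 0.01% and the families used by the prevalent-
disease exclusions (E10/E14, I10-I15) plus the pregnancy (O) and perinatal
(P) chapters. Whether the source analysis pooled or stratified its
propensity model by year is not stated; pooling with a year covariate is
the parsimonious reading of a covariate list that includes calendar year,
and a per-year fit is a trivial configuration away. Weights are not
truncated by default (stabilization alone controls them here); symmetric
percentile truncation is available.

One estimation detail deserves emphasis because it was learned the hard
way. The stabilized numerator `P(A = a | year)` deliberately preserves
between-year differences in arm shares. Uptake drifts strongly across
years (early years exhaust the likely participators), and the risk mix of
the eligible pool drifts with it, so pooling years with only `A` and `s(k)`
in the outcome model mixes years differently in the two arms and biases
the pooled contrast even when every baseline covariate is balanced
within year. The marginal-structural-model remedy is standard: any
covariate in the weight numerator must appear in the outcome model, hence
the `g_fy` main effects. Cumulative incidence is then standardized over
the weighted entry-year mix:

```
CI_a(K) = sum_y share_y * [1 - prod_{k<=K} (1 - lambda(k; a, y))]
```

and the reported risk difference is `CI_1(K) - CI_0(K)` at the 10-year
horizon. The crude comparator is the univariable analogue (no weights, no
year effects), with a continuous-time proportional-hazards fit available as
an independent cross-check; in the rare-event regime the two crude
estimates agree to within about 2%.

Confidence intervals are percentile intervals from a nonparametric
bootstrap that resamples unique persons — not entries or person-periods —
because one person appears in several nested trials and their periods are
serially dependent. Each replicate refits the propensity model, recomputes
the weights and refits the hazard model under the resampled person
multiplicities (frequency-weighted refits are likelihood-identical to
duplicating rows). Covariate selection via the prevalence floor and the
resource-use percentile are treated as fixed design steps, not re-estimated
per replicate. 1000 replicates is the reference setting, with 200 used
where the computational burden is high. Replicates that fail (separation)
are skipped and counted; more than 10% failures aborts.

The per-protocol sensitivity analysis artificially censors non-SHC entries
at the interval of their first checkup and re-weights the remaining
person-time by stabilized inverse-probability-of-censoring weights: a
pooled logistic model of remaining uncensored per interval on the baseline
covariates and the time spline (numerator model: intercept and spline
only), accumulated as a cumulative product within entry.

## Bias audit

Depression (F32/F34/F35, no medication requirement) serves as a negative-
control outcome: it shares the confounding structure of the primary outcome
but is not plausibly affected by checkup participation, so a non-null
negative-control HR measures residual bias. The audit divides the primary
HR by the negative-control HR on the log scale, with the combined interval
from independently-recovered standard errors
(`SE = (log U - log L) / (2 * 1.96)`). Because the composite outcome is
common rather than rare, the calibrated HR is converted to
an approximate risk ratio with the square-root transformation
`RR = (1 - 0.5^sqrt(HR)) / (1 - 0.5^sqrt(1/HR))` before applying the
E-value formula `E = RR* + sqrt(RR* (RR* - 1))`, `RR* = max(RR, 1/RR)`; the
rare-outcome shortcut (RR = HR) overstates the E-value here and is only
available behind `outcome_rare = TRUE`. The E-value for a confidence bound
uses the calibrated limit closest to 1 and is infinite when the calibrated
interval crosses 1 (no finite confounder strength is excluded).

## The synthetic claims generator

The real source database is proprietary, so the package ships a generator
(`generate_population()`) that reproduces the *structure* the pipeline
assumes, with known ground truth:

* persons with enrollment spans, geometric disenrollment
  (`annual_disenroll_prob = 0.05`, giving a median follow-up of roughly
  four years against the administrative end), yearly outpatient visits
  (mean about 3.5, mildly higher for sicker persons) and occasional
  hospitalizations;
* five baseline confounders — sex (70% female, reflecting the dependent-
  heavy insured population), employment (35%), age (uniform 40-70 at the
  first program year), and two coded history factors (a metabolic-risk
  marker E66, 30%; a mental-health marker F41, 15%) — each with uptake and
  outcome effects on the log-odds scale chosen to put the unweighted
  between-arm standardized mean differences in the 0.3-0.7 range reported
  for real checkup cohorts;
* a sixth, dominant uptake driver: a preventive-care-seeking indicator
  (35%, surfaced as code Z00) with a +3.0 log-odds uptake effect and no
  outcome effect. Concentrating uptake heterogeneity on an observed,
  outcome-neutral factor keeps the yearly first-uptake model exactly
  logistic in the measured covariates (so the propensity model is correctly
  specified) while making likely participators take up within their first
  eligible years — non-SHC entrants are then mostly low-propensity people
  and post-entry crossover stays a small fraction of non-SHC person-time,
  which keeps the intention-to-treat estimand close to the
  always-versus-never oracle contrast;
* yearly Bernoulli outcome onset on the logit scale
  (`baseline_annual_outcome_hazard = 0.015`), switching to the treated
  logit from the fiscal year of first checkup onward (persistent exposure,
  matching the ITT estimand), with true conditional hazard ratio
  `exp(log_hr_treatment) = 0.90` by default; onset writes a diagnosis code
  (E14 or I10) and its matching dispensing on the same date, so the
  code-plus-drug outcome rule fires unambiguously and pre-entry onsets are
  caught by the baseline exclusions;
* a negative-control onset process (F32, `0.008`/year) with the same
  confounder loadings and zero treatment effect; an optional standard-
  normal latent health-seeking factor with configurable loadings on uptake
  and on both outcome hazards (`unmeasured_effect_*`, 0 by default) powers
  the bias-audit scenarios;
* background benign diagnosis codes (rhinitis, URI, refraction disorders,
  and so on) recorded with person-level propensities tied to the
  confounders, so the high-dimensional part of the propensity model has
  genuine signal; about 5% prevalent cases coded shortly after enrollment
  exercise the exclusion rules; checkup records carry BMI, waist, blood
  pressure, HbA1c and smoking with realistic missingness (12.7% for HbA1c).

Everything is drawn from one seeded generator in a fixed vectorized order:
identical configuration and seed give byte-identical tables. The
Monte-Carlo oracle (`ground_truth()`) draws covariates only and computes
each person's counterfactual survival curves in closed form under
"checkup from the first year" versus "never", then summarizes the two
curve families as a discrete-time marginal hazard ratio by the same pooled
logistic machinery, with a block-split Monte-Carlo standard error.

What the generator does **not** emulate: measurement error in checkup
values, mortality as distinct from disenrollment, seasonal or within-year
timing structure, realistic breadth of Japanese claims coding, and any
effect heterogeneity over time or dose. Passing the recovery tests
therefore shows the estimator chain is correct under the assumed
structure — confounded uptake on fully observed covariates — not that the
real-data estimates are right; with the latent factor switched on, the
same pipeline is *designed* to be biased, which is what the negative-
control audit detects.

## Numerical choices and conventions

* Dates are day-resolution `Date`s; intervals are half-open `[start, end)`;
  ages are completed years at entry; fiscal year `y` is April 1 `y` to
  March 31 `y+1`.
* Annual intervals are 365.25 days (monthly: 365.25/12), so period
  boundaries do not drift across the decade.
* Quantiles, medians and IQRs use linear interpolation (R type 7)
  throughout, except the resource-use exclusion threshold, which uses the
  inverse-ECDF quantile (type 1) so that only persons strictly above the
  empirical percentile value are dropped — with an interpolated quantile
  the top user would be excluded even from a cohort of two.
* Logistic fits use iteratively reweighted least squares on the normal
  equations with step-halving, pivoted-QR dropping of collinear columns,
  and a tiny ridge only if the information matrix is numerically singular;
  fitted probabilities outside `[1e-8, 1 - 1e-8]` raise a separation flag.
  Aggregated cells enter as event fractions with binomial prior weights,
  which is likelihood-identical to row-level fits.
* The treatment-by-time interaction option is linear in interval index
  (`A * k`), the simplest shape that lets the hazard ratio drift over
  follow-up; the dose option adds cumulative checkup sessions (always 0 in
  the non-SHC arm) as a time-dependent covariate.
* All randomness flows from explicit integer seeds; the pipeline is
  deterministic end to end given (config, seed).

## Problem sizes used by the test suite

The recovery and balance properties are exercised at 50,000 persons
(parameter recovery, 200 bootstrap replicates), 20,000 persons (null
safety as a 5-experiment binomial coverage check; confounder balance), and
4,000 persons for the shared structural fixtures — sizes at which the
Monte-Carlo error of each check is small relative to its tolerance while
the whole suite stays comfortably interactive.

## Known limitations

* The hazard-ratio estimate is an odds ratio on yearly risks; at hazards
  far above a few percent per interval the approximation to a
  continuous-time hazard ratio degrades.
* The per-protocol censoring model uses baseline covariates plus time
  only; truly time-varying predictors of adherence are out of scope.
* The bias calibration assumes the negative control shares the full
  confounding structure of the primary outcome on the log-HR scale and
  that the two estimates are independent; both are approximations.
* Competing risks (death) are folded into censoring, as in the design
  being emulated.
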