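# seqtte

Sequential target-trial emulation for longitudinal claims data, built for
the question: does participating in a universal annual health checkup
(Japan's Specific Health Checkup, SHC) lower the risk of incident type 2
diabetes and hypertension? The package is for epidemiologists and
biostatisticians who want the full pipeline — nested per-fiscal-year cohort
construction from claims tables, stabilized inverse-probability weighting,
discrete-time pooled logistic hazard models, per-protocol censoring
weights, and a negative-control bias audit — as tested, reusable functions
rather than a one-off analysis script.

## The design and the model

Each fiscal year defines one emulated trial: persons aged 40–74 with ≥12
months of enrollment, ≥1 medical visit in the past year, no checkup
history, and no prevalent diabetes (ICD-10 E10/E14 + ATC A10) or
hypertension (I10–I15 + C02/C03/C07–C09) enter at April 1; those with a
checkup record that fiscal year are the SHC arm. Follow-up is discretized
into yearly intervals and the hazard is modelled by weighted pooled
logistic regression

    logit λ(k | A, y) = β₀ + β_A·A + s(k) + γ_y

with `A` assignment, `s(k)` a restricted cubic spline of time-in-study and
`γ_y` trial-year effects; `exp(β_A)` approximates the hazard ratio (HR)
for rare per-interval events. Stabilized weights
`sw = P(A=a|year)/P(A=a|L)` from a pooled logistic propensity model (age,
sex, year, employment, visit and hospitalization categories, and hundreds
of 3-digit ICD-10 history indicators) balance the arms; cumulative
incidence `CI_a(K) = Σ_y share_y · [1 − Π_k (1 − λ(k|a,y))]` is
standardized over the entry-year mix, and 95% CIs come from a bootstrap
that resamples unique persons. A depression negative-control outcome
(F32/F34/F35), the bias-calibrated ratio `HR_primary / HR_nc`, the
common-outcome conversion `RR = (1−0.5^√HR)/(1−0.5^√(1/HR))` and the
E-value `RR* + √(RR*(RR*−1))` quantify residual bias.

Because the source database is proprietary, the package ships a synthetic
claims generator with confounded checkup uptake, a known treatment effect
(default conditional HR 0.90), a null-effect negative control, and a
Monte-Carlo oracle for the marginal HR — so every stage of the pipeline is
validated against ground truth.

## Worked example

```r
library(seqtte)

cfg <- sim_config(n_persons = 8000, seed = 42)   # true conditional HR 0.90
db  <- generate_population(cfg)                  # persons / claims / checkups
res <- run_emulation(list(db = db, n_boot = 200, bias_audit = TRUE,
                          seed = 42))
print(res$estimate)
print(res$bias_audit)
ground_truth(cfg, n_mc = 100000, seed = 42)$true_marginal_hr
```

which prints:

```
IPW-adjusted HR: 0.8843  (95% CI 0.6558-1.132)
Risk difference at horizon: -1.56 %
Crude HR: 1.123
Negative-control HR: 0.9616
Bias-calibrated HR: 0.9196  (95% CI 0.5322-1.589)
Approximate RR: 0.9436   E-value: 1.312
[1] 0.908
```

Reading it: the crude HR (1.12) is badly confounded — checkup takers are
more often employed, male and metabolically coded, all of which also raise
outcome risk — while the weighted estimate (0.88, CI 0.66–1.13) recovers
the oracle marginal HR of 0.908 built into the generator. The
negative-control HR sits near 1 (no unmeasured confounding was simulated),
so the calibrated HR barely moves, and the E-value of 1.31 says an
unmeasured confounder would need risk-ratio associations of that strength
with both uptake and outcome to explain the calibrated estimate away. At
this deliberately small n the interval is wide; the test suite runs the
same recovery at 50,000 persons.

Individual stages are plain functions when you want only a piece:
`screen_fiscal_year()`, `build_sequential_cohort()`,
`baseline_covariates()`, `expand_person_periods()`, `fit_propensity()`,
`stabilized_weights()`, `balance_report()`, `ipcw_weights()`,
`fit_pooled_logistic()`, `cumulative_incidence()`, `bootstrap_cis()`,
`calibrate_hr()`, `hr_to_rr_common()`, `e_value()`.

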