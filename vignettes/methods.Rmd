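---
title: "Methods: kidney failure risk after AKI under competing risks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kidney failure risk after AKI under competing risks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

People already under nephrology clinic care are routinely counselled about
their risk of kidney failure, usually with absolute-risk tools such as the
kidney failure risk equation (KFRE). Two complications make this setting
awkward for standard prediction tools. First, these patients have frequent
protocolized creatinine testing, so small acute rises in creatinine —
episodes of acute kidney injury (AKI) — are often detected incidentally,
and it is unclear whether a history of AKI should change a 5-year kidney
failure prediction. Second, death is a strong competing risk: many patients
with AKI die before they can ever reach kidney failure, so naive
survival-analysis summaries overstate kidney failure risk.

`renalrisk` implements the full analytical chain for this question on
synthetic data: AKI e-alert detection over longitudinal creatinine,
landmark cohort construction, cause-specific and subdistribution hazard
modelling, evaluation of the published 5-year KFRE against refitted
competing-risk models with and without AKI, and decision-curve analysis.

## Clinical-algorithmic definitions

**eGFR.** The 2009 CKD-EPI creatinine equation, with creatinine converted
at 1 mg/dL = 88.4 µmol/L. The race coefficient is omitted: the data model
carries no race variable, and contemporary practice has moved away from it.
This is a documented deviation from the 2009 publication.

**AKI detection** (`detect_aki()`) applies a three-criterion hierarchy to
every measurement: (i) creatinine ≥ 1.5 × the median of all values 8–90
days earlier (91–365 days earlier when the medium window holds no tests);
(ii) ≥ 1.5 × the lowest value within 7 days; (iii) a rise of more than
26 µmol/L above the lowest value within 48 h. The lowest-numbered satisfied
criterion is recorded. Reference windows are strictly prior to the index
day, so detection starts at the second measurement. Consecutive triggers
closer than 30 days merge into one episode; the merge gap is a convention
of this package (no guideline defines when triggers become a distinct
recurrent episode), is configurable, and is logged prominently in
`aki_config()`. Staging follows standard KDIGO thresholds: stage 3 at peak
ratio ≥ 3 or creatinine ≥ 353.6 µmol/L, stage 2 at ratio 2.0–2.9, else
stage 1.

**Outcome adjudication** (`adjudicate_outcome()`). Kidney failure is
long-term RRT or eGFR < 15 mL/min/1.73 m² sustained for at least 90 days.
"Sustained" requires a confirmatory measurement at least 90 days after the
index low value with no intervening value at or above the threshold; a
patient who dies during an unconfirmed low period is adjudicated as a
death. This is a deliberately conservative, testable reading — an
alternative (counting unconfirmed lows as kidney failure) would both
inflate event counts and be unfalsifiable from lab data. Kidney failure and
death on the same day resolve to kidney failure. Times are integer days
divided by 365.25.

**Landmark design** (`build_landmark_cohort()`). Follow-up starts at day
730, after a 2-year observation window in which AKI exposure accrues.
Patients who die, start RRT, or establish sustained eGFR < 15 before the
landmark are excluded — this is what removes immortal time bias. Landmark
eGFR is taken from the last creatinine at or before day 730 (deliberately
*after* AKI episodes have had time to recover, so non-recovery is not
confused with progression); the 5-year clock runs from the landmark with
administrative censoring at 5 years.

## Models

Cause-specific Cox models (`fit_cox_cause_specific()`) treat other-cause
events as censored; Fine–Gray subdistribution models (`fit_fine_gray()`)
keep competing-event subjects in later risk sets with Kaplan–Meier
inverse-probability-of-censoring weights, and are the basis for absolute
5-year risk. Partial-likelihood maximization is delegated to the
`survival` package with Efron tie handling (day-granular data tie heavily;
Efron is the better standard default) and convergence tolerance 1e-9 with
at most 100 iterations. The IPCW censoring distribution is estimated
overall, not covariate-dependent: in this design censoring is almost
entirely administrative at 5 years, where weights are constant anyway.

The stepwise covariate ladder mirrors the clinical analysis: exposure
alone; + age (linear, per decade, centred at 70) and sex; + eGFR as an
inverse-square term; + four KDIGO albuminuria categories; + primary renal
diagnosis. The eGFR term is implemented as (30/eGFR)², proportional to
eGFR⁻² but scaled so the coefficient is O(1); this is a pure
reparameterization. No fractional-polynomial search is performed: the
transform family is fixed (a deliberate non-goal).

Refitted risk models (`refit_model()`) use age (per decade, centred 70),
eGFR (per 5 units, centred 30), sex, and continuous lnACR, optionally
adding the 2-year AKI flag. The baseline subdistribution survival S0 is
anchored at the all-zero design point — age 70, female, eGFR 30, ACR
1 mg/g, no AKI — rather than at covariate means, so the fitted model prints
in the exact algebraic form `1 − S0^exp(Σ βᵢ(xᵢ − cᵢ))`. Apparent
calibration of such a fit on its own data is exactly 1: the one-parameter
family α·LP has its partial-likelihood maximum at α = 1 because the score
at the MLE is zero. This identity is used as an exactness check.

**Missing ACR.** The proportion of patients without a tested ACR is large
(~35%). For the stepwise hazard models, "not tested" is its own
albuminuria category, so all rows are retained. For the continuous-lnACR
prediction models the package defaults to complete-case restriction. How
the original analysis handled untested ACR in its continuous models is not
stated anywhere we could find; complete-case is the only reconstruction
that does not invent data, but it is a known deviation risk and is surfaced
in the function documentation.

## Evaluation

Discrimination is the Mann–Whitney AUC of predictions against the
determinate binary 5-year outcome (kidney failure by 5 years vs known
event-free at 5 years); death before kidney failure counts as "no event",
consistent with the cumulative-incidence prediction target. Under the
generator's administrative-censoring-only design every subject is
determinate; with real data, indeterminate subjects are excluded and
counted. AUC comparisons between nested models on the same subjects use
the DeLong paired variance. The calibration slope is the coefficient of
the model's linear predictor in a one-covariate Fine–Gray model; deciles of
predicted risk give the calibration plot data. Decision curves use net
benefit TP/n − (FP/n)·p_t/(1−p_t) over a default 0–10% threshold grid in
0.1% steps, with treat-all and treat-none references.

## The synthetic world

`generate_cohort()` emulates a nephrology clinic registry. Stated-world
choices, fixed once:

* **Covariate margins** follow the published cohort tables: age bands
  22/58/20% (<60 / 60–79 / ≥80), 54% male, eGFR bands 36/39/15/10%
  (<30 / 30–44 / 45–59 / ≥60), diagnosis mix, 60% diabetes. ACR is
  lognormal(meanlog 4.45, sdlog 2.28) — solved so the tested-ACR category
  shares (29% severe, 39% moderate, 32% none/mild) match the table — with
  35.15% missing at random.
* **Visit process**: a jittered regular grid (60-day mean interval, ±25%
  uniform jitter, day 0 always tested), mirroring protocolized testing;
  clinic guidelines put CKD stage 3b–4 monitoring between monthly and
  half-yearly, and the source does not report its empirical test-frequency
  distribution, so 60 days is a stated assumption.
* **Measurement noise** is multiplicative lognormal with CV 5%
  (within-person analytic plus biological variation of serum creatinine is
  typically 5–8%); multiplicative keeps values positive and CV-stable.
* **AKI episodes**: counts are negative-binomial per patient (gamma frailty
  with dispersion 0.35), with the yearly rate 0.0881 calibrated so that
  P(≥1 episode in 2 years) = 13.3%, the published AKI prevalence. The
  frailty makes episodes cluster within patients, so roughly a quarter of
  AKI patients have recurrent episodes — consistent with the clinical
  literature on AKI recurrence; a plain Poisson process would make
  recurrence implausibly rare (~7%). Episode days are spaced ≥ 120 days
  apart inside [40, 680] so spikes are individually detectable. Peak
  factors are drawn inside each KDIGO stage band but away from the 1.5
  detection boundary (1.6–1.9 / 2.1–2.9 / 3.1–4.0) so that 5% noise rarely
  flips detectability; spikes decay with a 7-day half-life, and 30% of
  episodes leave a permanent creatinine plateau (×1.05–1.30), which is what
  couples AKI to lower landmark eGFR. By default covariates are sampled
  independently; `aki_link` optionally tilts AKI intensity by diabetes,
  ACR and eGFR to create genuine confounding (used to demonstrate the
  unadjusted → adjusted attenuation).
* **Outcomes** are exponential cause-specific hazards at the landmark with
  log hazard ratios taken from the published adjusted estimates (kidney
  failure 1.35 / death 1.89 for AKI at eGFR ≥ 30; 1.05 / 1.43 below 30;
  total recurrent-AKI effect 2.34) plus age/sex/eGFR/proteinuria effects
  with published signs and magnitudes fixed once; baseline rates were
  chosen to roughly reproduce the published 5-year outcome margins per
  eGFR stratum (and were not revisited afterwards). The proteinuria effect
  acts on the *observed KDIGO albuminuria category* (fixed surrogate levels
  ln 10 / ln 95 / ln 600, not-tested at the reference) rather than on
  continuous lnACR. This matters: the parameter-recovery targets require
  the analysis model and the generating truth to share a covariate set,
  and the stepwise analysis adjusts proteinuria by category. Hazard ratios
  are non-collapsible, so a truth acting on continuous lnACR would make
  the category-adjusted coefficient a systematically smaller estimand
  (~5% for the recurrent-AKI effect) than the generating log-HR — a
  mismatch between estimand and target, not an estimator defect.
  Kidney-failure events enter the registry as RRT start days, so
  adjudication recovers the simulated event exactly.

What the generator does **not** emulate — and hence what a green test does
not establish: no post-landmark creatinine series (so the sustained
eGFR < 15 and 30%-decline pathways are exercised only by hand-built
fixtures, and on generated data the decline-30 endpoint coincides with the
RRT-driven endpoint), no pre-landmark deaths or RRT (exclusion logic is
fixture-tested), no hospitalization or medication structure, no secular
trends, exponential (constant-hazard) event times, and exposure
misclassification is limited to what 5% noise induces (~0.1%). Parameter
recovery on this world validates the estimation chain, not the original
cohort's effect estimates.

## Numerical choices

* CKD-EPI inversion by bisection to 0.01 µmol/L (avoids piecewise inverse
  bookkeeping); round-trip error < 0.1 eGFR units.
* Median ties use R's standard midpoint rule (ties were unspecified in the
  source definition).
* Cox/Fine–Gray: Efron ties, eps 1e-9, max 100 iterations; coefficients
  with |β| > 50 raise a monotone-likelihood error.
* Wald 95% intervals on the log-HR scale throughout.
* Creatinine written to labs at 0.1 µmol/L resolution.
* Seeds: every stochastic operation takes an explicit seed; the scenario
  default is 20180915, and derived seeds stay below 2³¹.

## Known limitations

Episode truth in the generator is per-patient (flags), not per-episode
matched to detections; detector exactness is therefore tested on
noise-free schedules. The Fine–Gray weights are truncated only by the
5-year administrative horizon. The decision-curve dominance of the true
generating risk is asserted with a small Monte-Carlo slack. The pipeline's
table layouts are plain CSV mirrors of the published table structure, not
typeset reproductions.
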