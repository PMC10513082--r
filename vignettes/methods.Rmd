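---
title: "Methods: simulating the cost-effectiveness of GLP-1 receptor agonists in type 2 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating the cost-effectiveness of GLP-1 receptor agonists in type 2 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glp1sim)
```

## The decision problem

Chinese adults with type 2 diabetes inadequately controlled on metformin
can receive one of six GLP-1 receptor agonists (exenatide, liraglutide,
loxenatide, dulaglutide, semaglutide, lixisenatide) as add-on therapy.
The drugs differ in price, dosing, adverse-event profile and in how much
they lower HbA1c, BMI and blood pressure over the first six months.  Those
short-term differences propagate into different lifetime rates of diabetic
complications, and therefore different lifetime costs and quality-adjusted
life years (QALYs).  `glp1sim` implements the full decision-analytic
pipeline from a healthcare-system perspective: evidence synthesis, an
individual-level outcomes model, cost-effectiveness summaries and
uncertainty analysis.

The package's comparisons are expressed as net monetary benefit,
$NMB = \lambda \cdot QALY - Cost$, at a willingness-to-pay threshold of
$\lambda =$ USD 12,728 per QALY (China's 2021 per-capita GDP), and as the
incremental NMB (INMB) between arms.  ICERs are computed but flagged
unstable when QALY differences are very small, as they are between these
clinically similar regimens.

## Model structure

The simulation is an annual-cycle individual-level state-transition
model.  Each simulated patient carries the full risk-factor state (age,
sex, diabetes duration, smoking, HbA1c, BMI, SBP/DBP, lipids, renal
function, medication and comorbidity flags).  Per cycle, in order:

1. **Death** is drawn from a blended probability: the maximum of the
   all-cause-mortality risk equation and the natural (life-table)
   probability for the patient's age and sex.  The max rule floors
   diabetic mortality at population mortality; an additive-hazard blend
   would double-count background deaths.  Patients dying this cycle still
   live through it (end-of-cycle death), accruing the cycle's costs and
   utility plus a one-off end-of-life cost.
2. **Complication events** (MI, IHD, heart failure, stroke, PVD,
   neuropathy, amputation, skin ulcer, renal failure, cataract,
   retinopathy) are drawn from logistic-link annual risk equations.
   Chronic comorbidity flags are absorbing; severe hypoglycaemia recurs
   with its annual incidence.  Patients flagged to die this cycle skip new
   events (death is evaluated first).
3. **Accrual**: drug and routine therapy costs, complication costs split
   into event-year versus following-year amounts (renal failure is costed
   per year, retinopathy per event, hypoglycaemia per event), and the
   cycle utility
   `1 − base T2DM disutility − comorbidity disutilities − AE disutility
   (first year only) − BMI-deviation term`, floored at 0 and capped at 1.
4. **Progression**: deterministic annual drift of HbA1c (+0.1 %/yr),
   BMI (+0.1 kg/m²/yr), SBP (+0.5 mmHg/yr) and DBP (+0.2 mmHg/yr), and
   age/duration increments.  The drifts are configurable; the defaults are
   of the magnitude used by established diabetes outcome models for
   untreated risk-factor deterioration.

Treatment enters in three places: the six-month change rates multiply the
four risk factors once at entry (`state × (1 + rate)`); the arm's
adverse-event profile (events with trial rates above 5 % plus
hypoglycaemia) applies a grade-1/2 disutility in the first year; and the
arm's dosing schedule drives drug cost.  After five years every arm
switches to insulin glargine 8 IU/day plus a duration-dependent
antidiabetic therapy cost, reflecting progressive beta-cell failure; no
renewed treatment effect applies after the switch.

Costs and QALYs are discounted at 5 %/yr with end-of-cycle convention
(cycle *t* divided by $(1+r)^t$, *t* starting at 1) and no half-cycle
correction; the convention is documented and the rate is itself a
parameter varied in sensitivity analysis (0–8 %).  The lifetime horizon
is implemented as 100 annual cycles, which carries every starting age past
110 given the life table's terminal probabilities; survivors at the
horizon are flagged censored rather than force-killed.

## Parameters and their uncertainty

`default_parameters()` loads the packaged table of 129 parameters
(clinical baselines, AE rates, unit costs in USD converted once from CNY
at 6.693, and disutilities), each with a point value, a range read as a
central 95 % interval, and a distribution family: gamma for costs and
positive clinical quantities, beta for probabilities/proportions/
utilities, normal for relative effects.  `fit_distribution()` matches the
mean exactly and fits the interval by least squares (several price rows
have mean equal to the upper bound, so mean and interval are jointly
infeasible; matching the mean preserves the base case).  Zero-width
ranges become point masses.  One transcription choice: the renal-failure
disutility row is printed with a mean above its upper bound in the source
table; the upper bound is clamped to the mean, mirroring the price rows.

Parameters are sampled independently in the PSA — the table supplies
marginals only, and no correlation structure is asserted.

Drug pricing follows pack content: daily cost = pack price × daily dose /
pack content, with titration weeks costed at the titration dose.  The
lixisenatide pack is taken as the marketed 14-dose (280 µg) pen; pricing
a single 20 µg dose at the full pen price would give an implausible
14,000 USD/year.  Loxenatide is dosed 100 µg/week, the dose used in its
phase-III trial and matching its 100 µg pack.  The per-unit BMI utility
terms are signed: decrements above the pre-treatment baseline BMI,
credits below it.

## Evidence synthesis

Six-month change rates for HbA1c, BMI, SBP and DBP are synthesised across
the nine-trial network by a Bayesian random-effects network meta-analysis:
normal likelihood on observed arm-level change rates (SE = SD/√n),
study-level baselines, basic parameters with normal(0, 100²) priors,
heterogeneity SD τ ~ uniform(0, 5), and the standard multi-arm
correction.  Sampling is delegated to JAGS via `rjags` — the
field-standard backend for this model class — with deterministic per-chain
seeds; diagnostics (split-chain Gelman–Rubin, node-splitting,
design-by-treatment) and all summaries are computed by the package.
Production settings are 4 chains × 50,000 kept draws after 10,000
burn-in; tests and desk runs use reduced lengths, which the fit records.

Two open choices were decided as follows.  The synthesis scale defaults
to **mean differences** of change rates; a log-ratio scale (risk-ratio
reading) is exposed but requires all-negative observed rates, since
mixed-sign change rates make the log map ill-defined.  The likelihood is
**arm-based**, which uses the per-arm dispersions directly.  Relative
effects are converted to absolute per-arm change rates by anchoring on a
reference arm's observed trial rate (`arm_effects()`); re-referencing is
an affine relabelling that leaves pairwise contrasts unchanged.

Node-splitting compares the direct estimate (pairwise fit of the studies
containing both treatments) with the indirect estimate (network fit with
those studies removed) via a normal-approximation two-sided p-value; the
sub-fits default to common-effect so the direct estimate stays identified
when only one direct study exists.  The design-by-treatment test is a
two-stage GLS decomposition with full within-study covariance;
$I^2 = \max(0, (Q - df)/Q) \times 100$.

## Synthetic stand-ins and what they do (and do not) show

Three inputs of the original analysis are not publicly available in
machine-readable form: the CHIME risk-equation coefficients, the census
life table, and the trial supplement's change rates.  The `synthetic`
module generates documented stand-ins:

* **Risk equations** (`gen_risk_coefficients()`): logistic-link equations
  over age, sex, duration, HbA1c, BMI, SBP, smoking, CKD stage and prior
  events, with intercepts solved in closed form so the annual probability
  at the reference patient equals a calibration target exactly.  Default
  targets convert the baseline comorbidity prevalences to annual
  incidences by dividing by the mean diabetes duration (6 years), floored
  at 0.002 for zero-prevalence outcomes; severe hypoglycaemia keeps its
  stated 0.01/yr.  Real coefficient files in the same JSON schema are
  drop-in replacements.
* **Life table** (`gen_life_table()`): Gompertz–Makeham,
  $q(x) = 1 - e^{-(a + b e^{cx})}$ with $a = 4\times10^{-4}$,
  $b = 3\times10^{-5}$, $c = 0.095$ and a 0.6 multiplier on $b$ for
  women — adult mortality of realistic magnitude (q ≈ 0.006 at 55,
  ≈ 0.06 at 80), monotone from age 30.
* **Trial network** (`gen_nma_dataset()`): the nine-study design
  structure with known true effects (HbA1c reductions of 11–16 %,
  strongest for loxenatide; BMI strongest for semaglutide), study-level
  random effects and sampling noise, so estimator recovery is testable.

Because these are stand-ins, the package's absolute outputs (lifetime
costs around USD 39–43k, QALYs around 10 at a 2,000-patient desk scale)
are *not* reproductions of the published absolute values, which depend on
the unpublished risk coefficients and census table.  What the test-suite
does establish is the machinery: calibration is exact, closed-form limits
are met to 1e-9, estimators recover known truths, and the in-source
arithmetic identities (breakdown sums, the NMB identity) hold at their
printed precision.  The qualitative base-case ordering — loxenatide
cheapest-and-most-effective, positive INMB versus exenatide, the
high-priced arms trailing — emerges from the same structural drivers as
in the source analysis (price and HbA1c control).

## Uncertainty analysis

* **One-way SA** (`one_way_sa()`): each parameter at its bounds with all
  else at base, INMB versus exenatide recomputed under identical random
  streams, entries sorted by range (top 10 by tornado convention).
* **PSA** (`run_psa()`): per iteration one joint parameter draw plus one
  normal draw of the NMA effects (posterior SDs), then all arms simulated
  with common random numbers.  The event-stream seed is also held fixed
  across iterations, so PSA spread is second-order (parameter)
  uncertainty only.  The per-iteration cohort is reduced (default 500–
  1,000) to keep 50,000 iterations feasible at cluster scale; desk runs
  use a few hundred iterations.
* **CEAC** (`compute_ceac()`): probability each arm maximises NMB over a
  0–40,000 USD grid (step 400); exact ties split uniformly so
  probabilities sum to one at every grid point.
* **Scenarios** (`scenario_horizons()`): truncation at 10/20/30/40 years
  under identical seeds; cost and QALY are non-decreasing in the horizon
  by construction.

INMB confidence intervals are percentile bootstrap over paired
per-patient differences (2,000 resamples); arm-level CIs are first-order
patient-level intervals.

## The burden GLM

`burden_analysis()` quantifies the association between inadequate control
and lifetime comorbidity burden on the simulator's per-patient output:
achieved HbA1c is dichotomised at 7 % and BMI at 25 kg/m², and cost and
disutility outcomes are regressed on the two indicators plus the
remaining patient characteristics (pooled across arms with an arm
covariate by default).  The cost outcome defaults to a gamma/log GLM,
the disutility outcome to gaussian/identity; effects are reported as
average marginal effects on the outcome scale, so the dollars-and-QALYs
summary does not depend on the link.  The fitter (`irls_fit()`) is an
explicit IRLS implementation converging on relative deviance change
below 1e-8; its gaussian-identity case equals ordinary least squares
exactly, and `stats::glm` is used as an independent cross-check in the
test-suite, never as the implementation.

## Numerical and reproducibility choices

* Every stochastic entry point takes a seed; child seeds for chains,
  iterations and bootstraps derive from it through a fixed integer map,
  and all derived seeds stay below 2³¹.
* Common random numbers: each cycle draws a fixed count of uniforms per
  purpose (death, 11 events, hypoglycaemia, 12 first-year AE slots) for
  every patient, alive or dead, so arms with the same seed consume
  identical streams and differ only through parameters.
* Degenerate inputs: point-mass parameters are skipped (with a warning)
  by the tornado; beta/gamma fits reject means outside their support by
  parameter name; the gamma burden GLM shifts non-positive outcomes by a
  recorded constant.
* Problem sizes in the shipped tests and acceptance script — cohorts of
  50–10,000, 200 PSA iterations × 200 patients, 4 × 10,000–25,000 MCMC
  draws — were chosen so the full suite runs in minutes on a single core
  while every stochastic tolerance (3 SE / 3 posterior SD) retains power;
  production-scale settings (30,000 patients, 50,000 iterations, 4 ×
  50,000 draws) are plain argument changes.

## Known limitations

* The risk equations are calibrated stand-ins: gradient magnitudes are
  documented defaults, not estimates; absolute event rates and thus
  absolute costs/QALYs inherit that uncertainty.
* Baseline covariates are sampled independently (marginals only), and
  within-year event timing is not modelled (annual cycles, no
  discrete-event clock inside a year).
* No adherence, discontinuation, or societal costs; AE effects are
  restricted to the first treatment year; events with trial rates below
  5 % are excluded, slightly understating costs.
* The heterogeneity SD of the NMA mixes slowly when the true
  heterogeneity is near zero (boundary posterior under a uniform prior);
  treatment-effect chains are unaffected.  Convergence is always
  reported, and flagged — never silently accepted — above R-hat 1.05.
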