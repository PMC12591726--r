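---
title: "Methods: simulating and evaluating a three-arm return-to-work trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating a three-arm return-to-work trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

trialecon implements a complete trial-based economic evaluation for
vocational rehabilitation trials: a synthetic three-arm cohort generator, the
standard 12-month effectiveness analyses, multiple imputation, societal
costing, and the cost-effectiveness / cost-utility / cost-benefit machinery
(SUR, bootstrap ICERs, CE planes, acceptability curves, return on
investment). This vignette documents the models, the defaults and why they
were chosen, the numerical decisions, and what the synthetic data can and
cannot show.

## The setting

Workers on long-term sick leave for musculoskeletal disorders receive usual
case management (UC) from the welfare administration; two low-intensity
add-ons are compared against it: motivational interviewing (UC+MI, delivered
by case workers) and a stratified vocational advice intervention (UC+SVAI,
delivered by physiotherapists). Outcomes over 12 months are sickness-absence
days, time to sustained return to work (RTW), monthly receipt of wage
replacement benefits, musculoskeletal health (MSK-HQ, 0–56), EQ-5D-5L
utilities, and per-participant societal costs. Because individual-level
registry data of such trials are not publicly depositable, every analysis in
the package runs against a generator that emulates the statistical structure
those analyses assume.

## The synthetic cohort generator

### Sustained-RTW trajectory

Each participant carries a monthly panel of absence fractions (share of
contracted hours absent). The month of sustained RTW is drawn from a
discrete-time proportional-hazards model
\[
S_{\text{arm}}(m) \;=\; S_0(m)^{\text{HR}},
\]
where \(S_0\) is the survival curve implied by the month-specific baseline
hazards (`default_monthly_hazard()`, back-derived from a 12-month "no
sustained RTW" curve typical of this population: roughly 43% of the
reference arm reach sustained RTW by month 6 and 81% by month 12) and HR is
the arm's `rtw_hazard_ratio`. Drawing directly on the PH scale means a Cox
model on the detected RTW times recovers the configured hazard ratio; the
tie-heavy monthly time scale costs roughly two percent attenuation under the
Efron approximation, well inside the ±10% recovery tolerance used by the
tests.

Before the RTW month the absence fraction stays at or above 0.5 — the trial
population is by construction on ≥50% sick leave — and decays from its
starting level (100% absence with probability 0.6, otherwise uniform on
0.5–0.9) towards the 0.5 floor with a monthly factor of 0.45 (graded RTW).
After RTW the fraction is zero except for one-month relapses (probability
0.05/month), which are only allowed after the four-month confirmation window
so that the detected event month equals the drawn one.

### The sustained-RTW detector

Sustained RTW is the first four-week period of 50–100% return to contracted
hours without relapse. On a monthly panel the package operationalizes this
as the first month `m` with absence below the 0.5 threshold that stays below
it for the three following months. The confirmation window is truncated at
the end of follow-up by default, so a drop sustained through month 12 counts
as an event; this keeps events possible in months 10–12, which a strict
full-window reading (`require_full_window = TRUE`, also provided) would
censor. Alternatives at other granularities (single qualifying month,
daily-resolution windows) are intentionally out of scope: the panel is
monthly because wage-replacement registries are.

### Registry day counts

The annual sickness-absence day count is the panel-implied sum of monthly
fractions times 20 compensated workdays per month, plus the arm's
`absence_day_shift` and a small registry-versus-panel discrepancy
(SD 15 days). Two points deserve emphasis:

* **Days are counted in compensated workdays** (about 240/year), matching
  the wage-based valuation of absenteeism (daily wages are per workday).
  Under the shipped defaults the reference arm's day distribution has median
  ≈85 with quartiles ≈49–117. A calendar-day convention would roughly
  multiply cost levels by 1.5 but leaves every between-arm contrast, sign
  and ordering unchanged; all acceptance-level checks are contrasts.
* **The additive shift acts on the day-count variable, not on the monthly
  fractions.** Rescaling fractions to absorb a shift would push pre-RTW
  months below the detector threshold and corrupt the hazard-ratio recovery;
  registry day counts and monthly status panels are separate extracts in
  real trials as well. The shipped intervention-arm shifts (−11.2 and −10.5
  days) are the residuals left after the day reduction already implied by
  the hazard ratios 1.17 and 1.27 (measured once at 50 000 participants per
  arm: −5.4 and −7.7 days), so the total generator-level contrasts are
  −15.6 and −17.6 days.

### Benefit receipt

The default coupling defines monthly benefit receipt as "any absence
recorded in the month" (`benefit_received = absence_fraction > 0`), the
"any benefit day" reading of a monthly registry; under it the monthly
benefit odds ratio is an emergent consequence of the absence trajectories.
Because a parameter that is never injected cannot be recovered, the
generator also offers `benefit_mode = "logistic"`, drawing each person-month
from a logit with month-specific baseline prevalence (the no-RTW survival
curve, so prevalence declines over follow-up) shifted by the arm's log odds
ratio; this is the mode the odds-ratio recovery checks use. The shipped
contrasts are 0.73 (UC+MI) and 0.74 (UC+SVAI).

### Costs, utilities, MSK-HQ, covariates

Healthcare components are zero-inflated gammas (primary: mean €1046, shape
1, 10% zeros; secondary: mean €141, shape 0.8, 70% zeros), scaled per arm by
`healthcare_cost_scale` (0.96 and 0.88). Unpaid-productivity hours are a
heavily skewed zero-inflated gamma (mean 186 h, shape 0.35, 50% zeros;
shadow price €15/h), scaled by `unpaid_cost_scale` (0.65 and 0.63).
Intervention costs are gamma with means €53 (MI) and €78 (SVAI) and SD €35;
the reference arm costs nothing. Absenteeism cost is **deterministically**
days × sex-stratified daily wage (defaults €240/€210 — configurable
placeholders, not any trial's confidential rates), so absenteeism dominates
societal costs by construction and the conservation identity
`total = sum(components)` holds exactly at every pipeline stage.

Utilities are truncated normal on \([-0.594, 1]\) (the EQ-5D-5L floor) with
12-month means 0.68 / 0.71 / 0.69 and SD 0.15. MSK-HQ starts at 27 (SD 8),
recovers by 5–7.5 points over follow-up, and adds the arm's
`mskhq_shift_12m` (0 / +2 / +3 points) ramped linearly in time, a
participant random intercept (SD 4) and residual noise (SD 5), rounded and
clipped to 0–56. Baseline covariates (age ≈ N(48, 10) in 18–67, 57% women,
37% higher education, workability ≈ N(3, 2.6) on 0–10, 39% high physical
activity, 75% employer follow-up, prior-year and baseline absence days
log-normal, 35% high-risk group label) match the descriptive profile of
this population.

### Missingness overlay

`impose_missingness()` is missing at random: the per-variable removal
probability is a logit of the configured rate shifted by centred age and sex
(never by the value removed), so the marginal rate matches the configured
one to within binomial error. The default rates (workability 0.6%, physical
activity 0.2%, baseline MSK-HQ 4%, employer follow-up 1.4%) reproduce the
handful of baseline gaps typical of registry-recruited trials of ~500
participants.

## Effectiveness analyses

All multi-arm contrasts come from **single three-arm models**, never
pairwise refits.

* **Absence days**: Mann–Whitney U (exact enumeration when both groups have
  ≤8 untied values, tie-corrected normal approximation otherwise) plus
  robust linear regression. "Robust" is Huber M-estimation with tuning
  constant 1.345 via `MASS::rlm`; its reported standard errors are the
  Huber asymptotic ones, and `method = "ols"` provides least squares with
  HC3 sandwich errors as the sensitivity path.
* **Time to sustained RTW**: Kaplan–Meier with Greenwood variance and
  log-log confidence intervals; log-rank across arms; Cox PH with Efron tie
  handling by default (monthly times are heavily tied; Breslow behind a
  flag).
* **Monthly benefits**: pooled person-month logit with month fixed effects
  and variance clustered on participant. A GEE formulation would give
  near-identical population-averaged estimates here; the pooled logit with
  cluster-robust variance was chosen for transparency and speed.
* **MSK-HQ**: linear mixed model, fixed effects arm, time, arm×time and
  baseline score. A model cannot simultaneously carry a scalar random
  intercept *and* a fully unstructured covariance (the former is a special
  case of the latter), so both variants are exposed: random intercept with
  independent residuals (`lme4::lmer`, the default) and a GLS fit with
  unstructured within-participant covariance (`nlme::gls`). Neither is
  asserted to be "the" specification; on balanced data they coincide.
* The adjusted covariate set everywhere is age, sex, education, prior-year
  absence days, workability, baseline MSK-HQ, physical activity and
  employer follow-up; whether ratio-scale models share this set is not
  fixed by convention, so sharing it is the default.
* No multiplicity adjustment is applied across the two pairwise contrasts,
  matching standard reporting of three-arm add-on trials.

## Multiple imputation

`mice_pmm()` is chained equations with predictive mean matching: each
incomplete variable is regressed on all other analysis variables, and every
missing entry receives the observed value of a donor drawn from the 5
nearest predicted means (donors and the 10 cycles are configurable; neither
is canonical, these are the common defaults). Matching is type 1 — the
predictions on the missing side use a coefficient vector drawn from its
approximate posterior — so between-imputation variability is propagated;
`match_type = 0` gives the deterministic variant the donor-oracle test
uses. Binary and categorical variables are matched on a linear score of
their numeric coding; since donors return observed values, imputed entries
are always members of the observed support and types survive. Cost
variables are imputed at component level and totals recomputed, which
preserves the conservation identity. A tiny ridge (1e-8 of the mean
diagonal) stabilizes the normal equations when chained regressors turn
collinear. `rubin_pool()` applies Rubin's rules with the Barnard–Rubin
degrees-of-freedom correction (classical large-sample df when
`df_complete = Inf`). Both outcomes and baseline covariates are imputed by
default; restrict the `variables` argument to impute outcomes only.

## Economic evaluation

* **SUR**: the cost and effect equations are estimated jointly. With
  identical regressors the coefficients equal per-equation least squares and
  the cross-equation residual covariance feeds the joint coefficient
  covariance \( \Sigma \otimes (X'X)^{-1} \); with distinct regressor sets a
  one-step feasible GLS is used.
* **Effect definitions**: for cost-effectiveness the effect is
  sickness-absence days *averted* and the cost side excludes absenteeism —
  the monetized effect itself — to avoid double counting, while keeping
  intervention, healthcare and unpaid-productivity costs. For cost-utility
  the effect is the QALY and the cost side is the total societal cost. The
  default QALY is the single-point construction (12-month utility × 1
  year), the literal reading of a 12-month-only measurement; the
  conventional trapezoid AUC over available timepoints is available via
  `qaly_method = "auc-linear"` because a single-point QALY over 12 months is
  methodologically unusual.
* **Bootstrap**: nonparametric, resampling participants with replacement
  within arm (preserving arm sizes, which the estimator conditions on).
  With an imputation stack, B replicates are split evenly across the M
  completed datasets and the clouds pooled; the reverse nesting — re-impute
  inside each resample of the incomplete data — is implemented behind
  `nesting = "impute_within_bootstrap"` but is an order of magnitude more
  expensive and makes no practical difference at these missingness rates.
  Replicates that turn a covariate collinear are redrawn (up to 100 times)
  and counted in a message.
* **CE plane and CEAC**: quadrants classify the sign of
  (Δeffect, Δcost); exact zeros — probability ~0 with continuous data — are
  assigned to the favourable side (zero Δeffect counts as effective, zero
  Δcost as cost-saving), so (0, negative) lands in the dominant southeast.
  The acceptability curve is the fraction of the cloud with positive net
  monetary benefit λ·ΔE − ΔC over a willingness-to-pay grid; the default
  grids are €0–100 000 by €1000 per QALY and €0–500 by €10 per absence day,
  spanning the range where the curves move.
* **Cost-benefit**: costs are incremental intervention costs; benefits are
  the monetized reductions in absenteeism, unpaid productivity and
  healthcare spending. NB = benefits − costs, BCR = benefits/costs,
  ROI = (benefits − costs)/costs × 100, so ROI ≡ (BCR − 1) × 100
  identically; the probability of positive return is the fraction of
  bootstrap NB draws above zero.

## Problem sizes and what the tests show

The test suite checks three kinds of claims at three scales. Small
hand-checkable fixtures (≤8 subjects) pin every estimator to an independent
oracle: exhaustive pair counting, hand product-limit and O−E/V enumeration,
brute-force partial-likelihood and logit-likelihood maximization, stacked
GLS matrix algebra, hand-worked Rubin decompositions and exhaustive donor
search. Parameter-recovery checks run at 5000 participants per arm, where
Monte-Carlo error is small against the pre-registered tolerances (±2 days
for the absence shift, ±10% relative for hazard and odds ratios). The
end-to-end sign-and-ordering check of the cost, CE and ROI tables runs the
full pipeline (MAR overlay, M = 5 imputations, B = 2000 bootstrap) at 4000
participants per arm: at the enrolled size of ~170 per arm the ordering of
the two interventions' net benefits is a coin-toss-plus under the
generator's own truth (the true gap is small against its sampling error),
exactly as the wide published intervals suggest, so orderings are asserted
at a size where the generator's truth is resolvable while the trial-scale
run in `analysis/` simply reports what it finds.

Passing these tests shows the estimators are correct and the pipeline is
coherent; it does **not** show the generator reproduces real registry data.
In particular the generator does not emulate: national EQ-5D-5L value-set
tariffs (utilities are consumed as numbers), recruitment refusal or
stratified randomization mechanics (arm labels and risk-group labels are
assigned directly), intervention content or fidelity, calendar-time
effects, clustering by case worker, or the day-level granularity of real
absence spells. Absenteeism cost *levels* depend on the workday convention
discussed above; contrasts do not.

## Reproducibility

A single master seed drives everything; each stage (simulation, missingness,
imputation, bootstrap) derives its own child seed by a fixed offset
(`stage_seed()`), so stages can be re-run independently from persisted
intermediates (plain CSV/JSON throughout). `run_pipeline()` writes a
manifest with the config checksum, seed, per-stage runtimes and file
inventory; identical config and seed reproduce identical outputs byte for
byte.
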