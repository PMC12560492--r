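---
title: "Time-sequenced causal mediation: models, rules and validation design"
author: "lcmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-sequenced causal mediation: models, rules and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcmediate)
```

## The problem

Childhood maltreatment — emotional, physical or sexual abuse, and emotional
or physical neglect — is consistently associated with adult mental and
somatic disease. A natural question is how much of that association runs
through modifiable behaviour: smoking and overweight. Answering it with
cross-sectional data is treacherous because the behaviours and the diseases
influence each other in both directions (disease onset commonly triggers
smoking cessation or weight change). `lcmediate` implements a mediation
pipeline in which mediator status is defined *strictly before* the outcome:
a participant counts as an ever smoker for a given disease only if their
reported smoking-initiation age precedes their age at first diagnosis, and
as early-onset overweight only if an overweight milestone (higher weight
than peers at age 10, or BMI ≥ 25 at age 18) precedes it.

The package has five parts: variable derivation from a participant-level
cohort table, a from-scratch GLM layer, a closed-form mediation engine with
a Monte-Carlo potential-outcome oracle, a study orchestrator, and a
synthetic cohort generator whose true mediation effects are available
analytically. Real cohort data of this kind are access-restricted, so the
generator is a first-class component: it is the ground truth against which
every stage is validated.

## Exposure and mediator derivation

**Exposures.** The five-item Childhood Trauma Screener is dichotomised at
the moderate/severe cut-offs: item ≥ 3 for emotional and physical abuse,
≥ 2 for sexual abuse, and ≤ 2 for the two *positively phrased* neglect
items. Abuse = any abuse item at or above its cut-off; neglect = either
neglect item at or below its cut-off. Records with a missing or
out-of-range item are excluded, never imputed.

**Reference age.** Mediator timing needs a reference age. For participants
with the disease under analysis it is the age at first diagnosis. The data
model carries no analogous anchor for unaffected participants, so they use
the baseline-examination age — "ever smoked by the time we observed you" is
the natural analogue of "ever smoked by diagnosis". This convention is a
documented assumption of the package, not a rule inherited from the data.

**Tie-breaks.** "Before" means strictly before: an initiation age or
milestone age equal to the reference age does not qualify. Overweight
milestones live at the assessment ages {10, 18, 30, 50}; the qualifying age
is the earliest satisfied milestone. BMI at 18/30/50 divides the recalled
weight by the squared baseline height, and the ≥ 25 threshold is applied
with an absolute tolerance of 1e-9 so a recorded weight implying a BMI of
exactly 25.0 qualifies despite floating-point division.

**Exclusions.** Analysis tables are complete-case. Each excluded row is
attributed to exactly one reason, assessed in a fixed order (missing CTS,
missing smoking history, missing weight history, missing disease history,
missing education, then missing diagnosis age and diagnosis before 18 among
cases, then variant-specific rules such as quitting before the diagnosis
under the current-smoking variant). The fixed order makes the
`exclusion_ledger` reproducible and exactly conserving:
input = retained + sum of exclusions, on every run.

**Cancer sub-outcomes.** The first tumour site is classified against two
fixed lists (smoking-related and obesity-related); breast counts as
smoking-related for women only. A cancer case whose site is outside the
requested class counts as a non-case of the sub-outcome, keeping the
denominator identical to the any-cancer analysis. Sites outside the
controlled vocabulary classify as neither and are counted in a warning.

## Regression layer

Binary outcomes and binary mediators on the risk-ratio scale are fitted
with a log-link GLM with Poisson working variance ("modified Poisson"
regression). With a binary outcome that working model is intentionally
misspecified, so all risk-ratio inference uses the sandwich covariance
(HC0 by default; HC1 adds the n/(n−p) factor). Mediator models inside the
mediation engine are logistic; age-at-diagnosis outcomes use ordinary
linear regression among affected participants.

The IRLS implementation standardises non-intercept columns internally,
starts from zero coefficients with the intercept at the link-transformed
response mean, step-halves on deviance increases, and stops when the score
norm on the standardised design falls below 1e-8 (at most 100 iterations).
Rank deficiency is reported with the names of the collinear columns;
logistic fits whose linear predictor exceeds 25 in absolute value are
rejected as separated. A log-Poisson fit on a binary outcome warns if any
fitted risk exceeds one. On saturated 2×2 layouts the fits reproduce the
textbook risk ratio and its robust variance
(1/e₁ − 1/n₁ + 1/e₀ − 1/n₀) to 1e-10, and on random data they agree with
`glm()` plus `sandwich::vcovHC`, which serve only as test oracles.

## Mediation engine

Let the outcome model be
log P(Y=1 | a, m, c) = θ₀ + θ₁a + θ₂m + θ₃am + θ₄ᵀc and the mediator model
logit P(M=1 | a, c) = β₀ + β₁a + β₂ᵀc. The counterfactual risk integrates
the binary mediator exactly — no rare-outcome approximation:

Q(a, a′; c) = exp(θ₀ + θ₁a + θ₄ᵀc) · [(1 − p(a′)) + p(a′)·exp(θ₂ + θ₃a)],

with p(x) = logistic(β₀ + β₁x + β₂ᵀc). The two-way decomposition reports
RR_PDE = Q(1,0)/Q(0,0), RR_TIE = Q(1,1)/Q(1,0), RR_TE = RR_PDE·RR_TIE, and
the proportion mediated PM = RR_PDE(RR_TIE − 1)/(RR_TE − 1). The four-way
decomposition splits the excess relative risk RR_TE − 1 into CDE, INT_ref,
PIE and INT_med with the mediator reference level m\* = 0 (never smoker /
never overweight); CDE + INT_ref equals RR_PDE − 1 and PIE + INT_med equals
RR_PDE(RR_TIE − 1), exactly, at the point estimates.

Two properties of this decomposition deserve emphasis because they are
easy to get wrong:

* PM is a ratio and legitimately falls outside [0, 1] when direct and
  indirect effects oppose or the total effect is near null; its interval is
  computed on the identity scale and may span hundreds of percent.
* The interaction components measure **additive** interaction. A log-link
  model without a product term (θ₃ = 0) still has additive interaction
  whenever θ₁ ≠ 0 and θ₂ ≠ 0, so INT_ref and INT_med do **not** vanish at
  θ₃ = 0; what does hold there is that the controlled direct effect equals
  the pure direct effect on the RR scale. The unit tests pin both facts
  against independently derived closed forms.

**Inference.** Default intervals are delta-method: central finite
differences (relative step 1e-6) of the effect with respect to the stacked
coefficient vector, with a block-diagonal joint covariance (sandwich block
for the outcome fit, model-based block for the logistic mediator fit),
matching separate-equation estimation. Risk ratios get normal intervals on
the log scale; PM and the excess-RR components on the identity scale. A
bootstrap option resamples rows and refits both models, capturing
cross-model correlation; on a fixed known-truth configuration the delta SE
of PM agrees with the bootstrap SD within a few percent.

**Conditioning.** Natural effects are conditional on covariates. The paper
tables of this literature report one effect per stratum without stating the
conditioning point, so the package evaluates at the covariate means of the
analysis table being decomposed (including indicator means), overridable
through `mediation_spec(c_cond = ...)` and recorded in every result.

**Oracle.** `monte_carlo_oracle()` simulates M(a\*) and Y(a, m) directly
from the two structural models and averages the potential-outcome
definitions of every estimand; it never calls the closed forms. Point
estimates are plug-in functionals of overall means (per-batch ratio
averaging was rejected: its Jensen bias reaches the magnitude of three
Monte-Carlo standard errors for near-null effects) and standard errors come
from a delete-one-batch jackknife over 50 batches, which correctly inflates
for unstable ratios such as PM when RR_TE ≈ 1.

**Calibration of the agreement tests.** The oracle-agreement suite compares
50 random valid coefficient sets × 8 estimands at 10⁶ draws. The z
statistics of an exact implementation are standard normal, so demanding
every one of the 400 comparisons fall within 3 SEs would fail a correct
implementation most of the time by order statistics alone. The suite
therefore bounds the *family*: the count of 3-SE exceedances must stay
within its binomial 99.5% envelope, no comparison may exceed the
Bonferroni-calibrated family-wise 1% bound (≈ 4.06 SEs), and the median z
must sit below 1. A genuinely biased closed form fails all three.

## Synthetic cohort generator

The generator emulates the participant table of a large population-based
baseline examination:

* **Exposures.** Abuse (16.32%) and neglect (14.93%) are drawn jointly;
  their overlap is a free knob (default joint probability 5.43%, matching a
  combined-maltreatment margin of 25.82%) because the field's tables report
  only the margins. CTS items are then generated consistently with the
  flags, so scoring recovers the exposures exactly.
* **Covariates.** Baseline age uniform on 19–75, sex 49.44% women, 18
  centers, education normal (rounded, clipped to 8–20), birth year =
  baseline year − age. Exact covariate shapes are immaterial to the
  estimands and are chosen for simplicity.
* **Mediators.** Ever smoking and early-onset overweight follow logistic
  models in the exposures. Intercepts and exposure coefficients are
  calibrated by damped fixed-point iteration so the implied *margins*
  (52.80% ever smoking, 17.09% early overweight) and *marginal risk ratios*
  (1.23/1.10 for abuse/neglect on smoking) hit their targets exactly in
  closed form.
* **Outcomes.** Seven diseases follow log-linear Bernoulli risks — Bernoulli
  draws with mean exp(linear predictor), not Poisson counts; the Poisson
  working likelihood is an estimation device, not a data model — with an
  exposure-by-mediator product term, each disease tied to one generative
  mediator (overweight for type-2 diabetes, smoking otherwise) so the
  single-mediator analysis matches the generative structure and the true
  effects stay in closed form. Intercepts are calibrated to the reference
  prevalences (1.2%–13.4%). Configurations whose risk could exceed one
  anywhere on the support are rejected by `validate_cohort_config()`.
* **Timing.** Event histories are generated *backwards from the mediator
  flag*: a generative ever smoker receives an initiation age truncated
  below every reference age of that participant, an early-overweight
  participant receives either a "higher weight at 10" report or a
  qualifying BMI at 18, and diagnosis ages are drawn within [19, baseline
  age]. Consequently the time-sequenced derivation recovers the generative
  mediator with probability 1 under the default configuration — the
  round-trip the test suite asserts row for row. Switches inject
  initiation-after-diagnosis records and under-18 diagnoses to exercise the
  filters, and missingness is completely at random, sufficient for testing
  complete-case exclusion accounting.
* **Covariate coefficients default to zero** in the generative mediator and
  outcome models: covariates appear in the data and are adjusted for in
  estimation, but margins, calibration and ground-truth effects remain
  analytic. Estimating coefficients whose true value is zero costs nothing
  asymptotically relevant at the sample sizes used.

What the generator deliberately does **not** emulate: age-dependent disease
risk, center-level effect heterogeneity, recall error in retrospective
weight and smoking histories, informative missingness, or sampling weights.
Passing the validation suite therefore demonstrates that the *pipeline* is
correct — estimands, derivation rules, variances — not that any particular
real-data estimate is.

`true_mediation_effects()` applies the engine's closed forms directly to
the generative coefficients, conditional on a covariate point and on the
non-analysed exposure (default 0). Under the default configuration the two
exposures are correlated and both act on mediator and outcome, so the
marginal association analysed for one exposure absorbs part of the other —
exactly as in the single-exposure analyses this design mirrors; the
parameter-recovery harness instead zeroes the second exposure's
coefficients so estimate and truth coincide.

## Study orchestration

`run_full_study()` enumerates disease × exposure × mediator variant ×
stratum, with strata {all, men, women, born ≤ 1970, born > 1970}. Sex
leaves the covariate set inside sex strata; birth-cohort strata keep
baseline age. The substantive-effect screen flags RR < 0.9 or RR > 1.1
(strict) and |β| > 1 year, and gates interpretation on all three paths
A (exposure→mediator), B (mediator→outcome), C (exposure→outcome) being
substantive; no multiple-testing adjustment is applied, matching the
screen-based interpretation this design follows. Cells with fewer than 10
outcome or mediator cases are marked not estimable rather than fitted
(IRLS is unstable there and no conclusion would be drawn anyway); cell
failures are recorded in the row, never aborting the run. Sensitivity
pairings exchange ever smoking for current smoking (quit-before-diagnosis
excluded) and early-onset overweight for its 18+ variant (age-10 route
dropped). Age-at-diagnosis mediation is implemented
(`mediate_linear_outcome()`, difference scale) but disabled by default in
the orchestrator. Reports are written with fixed two-decimal formatting and
a manifest without timestamps by default, so repeated runs with the same
seed are byte-identical.

## Problem sizes used in validation

The shipped validation suite uses: 50 coefficient sets × 10⁶ oracle draws
for closed-form agreement; 600 replicates at n = 5,000 for Wald coverage
of the robust risk-ratio intervals (accepted range 93–97%); 200 synthetic
cohorts of n = 20,000 (4 centers) for proportion-mediated recovery at a
true PM of 30% (mean within ±2 percentage points, ≥ 90% CI coverage) and at
a true PM of 0 (mean |PM| ≤ 1 point); and a full 9 × 2 × 2 × 5-cell study
on a calibrated cohort of n = 20,000 run twice to assert byte-identical
reports. These sizes are the package's chosen compromise between
Monte-Carlo resolution and a test suite that runs in minutes.

## Known limitations

* The joint covariance of the two fits is block-diagonal under delta
  inference; the bootstrap captures the cross-model correlation instead.
* Natural-effect identification assumes no unmeasured
  exposure–outcome, exposure–mediator or mediator–outcome confounding and
  no mediator–outcome confounder affected by exposure; none of that is
  testable here, and no E-value style sensitivity analysis is included.
* Mediators are analysed one at a time; joint mediation by smoking and
  overweight is out of scope.
* The generator's diagnosis ages are independent of covariates and
  exposures given the model terms; analyses of *age at diagnosis* on
  synthetic data therefore have null truth by construction.

## A minimal session

```{r example, eval = FALSE}
cfg <- cohort_config(n = 20000)
cohort <- generate_cohort(cfg, seed = 1)

tab <- build_analysis_table(cohort, "mi", "abuse", "ever_smoking")
exclusion_ledger(tab)

tab$center <- factor(tab$center)
covs <- c("baseline_age", "female", "education_years", "center")
out_fit <- fit_glm(tab, design_spec("y", c("a", "m", "a:m", covs), "log_poisson"))
med_fit <- fit_glm(tab, design_spec("m", c("a", covs), "logistic"))
pair <- mediation_models(out_fit, med_fit, "a", "m", data = tab)

two_way_decomposition(pair)
four_way_decomposition(pair)
true_mediation_effects(cfg, "mi", "abuse")
```
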