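# lcmediate

Time-sequenced causal mediation analysis for life-course cohort data.

`lcmediate` is for epidemiologists and biostatisticians asking how much of
the association between childhood adversity (abuse, neglect, scored from
the five-item Childhood Trauma Screener) and adult disease (cancer and its
smoking-/obesity-related subtypes, myocardial infarction, stroke, type-2
diabetes, COPD, anxiety, depression) runs through behavioural mediators —
smoking and overweight — whose onset can be dated *before* the age at first
diagnosis. Because disease onset itself changes smoking and weight, the
package defines mediator status strictly from pre-diagnosis events: an
ever smoker for a given disease is someone whose smoking-initiation age
precedes their age at first diagnosis; early-onset overweight requires a
higher weight than peers at age 10 or a BMI ≥ 25 at age 18, again before
diagnosis.

## The model

For binary outcome Y, binary mediator M, binary exposure A and covariates
c, the package fits

* outcome: log P(Y=1 | a, m, c) = θ₀ + θ₁a + θ₂m + θ₃am + θ₄ᵀc
  (log-link Poisson-mean GLM — "modified Poisson" — with sandwich SEs, so
  exp(coefficients) are risk ratios without a rare-outcome approximation),
* mediator: logit P(M=1 | a, c) = β₀ + β₁a + β₂ᵀc,

and integrates the mediator out exactly:

    Q(a, a′; c) = exp(θ₀ + θ₁a + θ₄ᵀc) · [(1 − p(a′)) + p(a′)·exp(θ₂ + θ₃a)],
    p(x) = expit(β₀ + β₁x + β₂ᵀc).

Reported estimands: RR_PDE = Q(1,0)/Q(0,0) (pure direct effect),
RR_TIE = Q(1,1)/Q(1,0) (total indirect effect),
RR_TE = RR_PDE·RR_TIE, the proportion mediated
PM = RR_PDE(RR_TIE−1)/(RR_TE−1), and the four-way decomposition of the
excess relative risk RR_TE − 1 into CDE + INT_ref + PIE + INT_med
(controlled direct effect, reference interaction, pure indirect effect,
mediated interaction). Intervals are delta-method (default) or bootstrap.
All GLMs are fitted by the package's own IRLS; `glm()` and
`sandwich::vcovHC` appear only as independent oracles in the tests, as
does a Monte-Carlo potential-outcome simulator for every closed form.

A synthetic cohort generator with analytically known ground truth
(`cohort_config()`, `generate_cohort()`, `true_mediation_effects()`)
reproduces the reference margins (abuse 16.32%, neglect 14.93%, ever
smoking 52.80% with an abuse risk ratio of 1.23, early overweight 17.09%,
disease prevalences 1.2–13.4%) and generates event histories so that the
time-sequenced derivation recovers the generative mediator exactly.

## Worked example

```r
library(lcmediate)

cfg    <- cohort_config(n = 20000)          # calibrated generator defaults
cohort <- generate_cohort(cfg, seed = 1)

tab <- build_analysis_table(cohort, "mi", "abuse", "ever_smoking")
tab$center <- factor(tab$center)
covs <- c("baseline_age", "female", "education_years", "center")
out_fit <- fit_glm(tab, design_spec("y", c("a", "m", "a:m", covs), "log_poisson"))
med_fit <- fit_glm(tab, design_spec("m", c("a", covs), "logistic"))
pair    <- mediation_models(out_fit, med_fit, "a", "m", data = tab)

two_way_decomposition(pair)
#> <two_way_result>  RR-scale natural effects (PM on the proportion scale)
#>        estimate   lower  upper     se
#> rr_te    1.2440  0.9267 1.6700 0.1502
#> rr_pde   1.1194  0.8293 1.5112 0.1531
#> rr_tie   1.1113  1.0449 1.1819 0.0314
#> pm       0.5105 -0.1639 1.1849 0.3441

four_way_decomposition(pair)
#> <four_way_result>  excess-RR components (sum = RR_TE - 1 = 0.244013 )
#>            estimate   lower  upper     se
#> err_cde     -0.0624 -0.4660 0.3412 0.2059
#> err_intref   0.1818 -0.1533 0.5169 0.1710
#> err_pie      0.0801  0.0479 0.1124 0.0165
#> err_intmed   0.0444 -0.0377 0.1266 0.0419

true_mediation_effects(cfg, "mi", "abuse")
#> <mediation_truth> mi / abuse 
#>      rr_te     rr_pde     rr_tie         pm    err_cde err_intref    err_pie 
#>    1.31095    1.21403    1.07984    0.31170    0.11469    0.09934    0.07496 
#> err_intmed 
#>    0.02196
```

Reading the output: at this conditioning point (covariate means), abuse
raises MI risk by an estimated 24% in total (RR_TE 1.24, CI crossing 1 at
n = 20,000); the indirect path through pre-diagnosis ever smoking carries
an 11% risk increase (RR_TIE 1.11), i.e. an estimated 51% of the excess
risk is mediated (PM, wide CI — PM intervals legitimately extend beyond
[0, 1]). The four components sum to RR_TE − 1 exactly. The last block shows
the generative truth implied by the configuration (conditional on the other
exposure being absent): the estimates straddle it within their intervals.

The full study — every disease × exposure × mediator × stratum cell, path
models A/B/C, the substantive-effect screen (RR < 0.9 or > 1.1, |β| > 1),
and both decompositions — runs with:

```r
res <- run_full_study(cohort, study_config())
export_report(res, "report")   # results.csv + manifest.json, byte-stable
```

A thin CLI over the same functions ships in `inst/cli/lcmediate.R`
(subcommands `simulate`, `derive`, `mediate`, `report`).

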