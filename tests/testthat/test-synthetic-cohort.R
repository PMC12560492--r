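test_that("configuration validation names each violated bound", {
  cfg <- cohort_config(n = 100L, calibrate = FALSE)
  # all-zero coefficients and prevalence 0.5 are valid (risk = exp(lambda0) <= 1)
  cfg0 <- cfg
  cfg0$exposure <- list(p_abuse = 0.5, p_neglect = 0.5, p_both = 0.25)
  for (d in names(cfg0$outcomes)) {
    cfg0$outcomes[[d]][c("lambda_abuse", "lambda_neglect", "lambda_med",
                         "lambda_abuse_med", "lambda_neglect_med")] <- 0
    cfg0$outcomes[[d]]$lambda0 <- -1
  }
  expect_identical(validate_cohort_config(cfg0), character(0))

  # a positive log-risk intercept pushes the risk above 1
  bad <- cfg0
  bad$outcomes$mi$lambda0 <- 0.1
  v <- validate_cohort_config(bad)
  expect_length(v, 1L)
  expect_match(v, "risk exceeds 1")
  expect_match(v, "mi")

  # probabilities outside [0, 1] are named
  bad2 <- cfg
  bad2$exposure$p_abuse <- 1.2
  v2 <- validate_cohort_config(bad2)
  expect_true(any(grepl("p_abuse", v2)))
  expect_error(generate_cohort(bad2), "p_abuse")
})

test_that("generation is seed-deterministic and respects n", {
  cfg <- cohort_config(n = 500L)
  c1 <- generate_cohort(cfg, seed = 11)
  c2 <- generate_cohort(cfg, seed = 11)
  expect_identical(c1, c2)
  expect_false(identical(c1, generate_cohort(cfg, seed = 12)))
  expect_equal(nrow(c1), 500L)

  cfg0 <- cohort_config(n = 0L)
  c0 <- generate_cohort(cfg0, seed = 1)
  expect_equal(nrow(c0), 0L)
  expect_setequal(names(c0), names(c1))
})

test_that("simulated margins match the configured targets at the binomial rate", {
  n <- 1e5
  cfg <- cohort_config(n = n)
  coh <- generate_cohort(cfg, seed = 2024)
  se <- function(p) sqrt(p * (1 - p) / n)
  sc <- score_cts(coh[, grep("^cts_", names(coh))])
  expect_lt(abs(mean(sc$abuse) - 0.1632), 3 * se(0.1632))
  expect_lt(abs(mean(sc$neglect) - 0.1493), 3 * se(0.1493))
  expect_lt(abs(mean(coh$ever_smoked) - 0.5280), 3 * se(0.5280))
  # the derived disease-specific mediator reproduces the margin too
  m <- derive_smoking_mediator(coh, "mi", "ever_smoking")
  expect_lt(abs(mean(m) - 0.5280), 3 * se(0.5280))
  ow <- derive_overweight_mediator(coh, "diabetes", "early_overweight")
  expect_lt(abs(mean(ow) - 0.1709), 3 * se(0.1709))
  # disease prevalences
  for (d in c("mi", "depression"))
    expect_lt(abs(mean(coh[[paste0("dx_", d)]]) - outcome_prevalence(cfg, d)),
              3 * se(outcome_prevalence(cfg, d)))
})

test_that("a null generative model yields empirical risk ratios of one", {
  cfg <- cohort_config(n = 8e4, calibrate = FALSE)
  for (m in names(cfg$mediators))
    cfg$mediators[[m]][c("gamma_abuse", "gamma_neglect")] <- list(0, 0)
  for (d in names(cfg$outcomes))
    cfg$outcomes[[d]][c("lambda_abuse", "lambda_neglect", "lambda_abuse_med",
                        "lambda_neglect_med")] <- list(0, 0, 0, 0)
  coh <- generate_cohort(cfg, seed = 8)
  for (d in c("mi", "depression")) {
    y <- coh[[paste0("dx_", d)]]
    p1 <- mean(y[coh$.abuse == 1]); p0 <- mean(y[coh$.abuse == 0])
    se_log_rr <- sqrt((1 - p1) / sum(y[coh$.abuse == 1]) +
                      (1 - p0) / sum(y[coh$.abuse == 0]))
    expect_lt(abs(log(p1 / p0)), 3 * se_log_rr)
  }
})

test_that("analytic ground truth obeys its limits and matches the oracle", {
  cfg <- recovery_config(0L)
  # no product term: true PDE equals the controlled direct effect on the
  # RR scale (the additive interaction components remain, as the log-link
  # model implies)
  cfg0 <- cfg
  cfg0$outcomes$mi$lambda_abuse_med <- 0
  tr0 <- true_mediation_effects(cfg0, "mi", "abuse")
  expect_equal(tr0$rr_pde, exp(cfg0$outcomes$mi$lambda_abuse), tolerance = 1e-12)
  # blocked mediator path: TIE = 1, PM = 0
  trb <- true_mediation_effects(recovery_config(0L, pm_target = 0), "mi", "abuse")
  expect_equal(trb$rr_tie, 1, tolerance = 1e-15)
  expect_equal(trb$pm, 0, tolerance = 1e-15)
  expect_error(true_mediation_effects(cfg, "gout", "abuse"), "unknown disease")

  # agreement with the potential-outcome simulation
  cfg$outcomes$mi[c("lambda0", "lambda_abuse", "lambda_med",
                    "lambda_abuse_med")] <- list(-4, 0.2, 0.6, 0.1)
  cfg$mediators$smoking[c("gamma0", "gamma_abuse")] <- list(-0.5, 0.4)
  tr <- true_mediation_effects(cfg, "mi", "abuse")
  or <- monte_carlo_oracle(c(-4, 0.2, 0.6, 0.1), c(-0.5, 0.4),
                           n_draws = 5e5, seed = 99)
  for (w in c("rr_te", "pm"))
    expect_lt(abs(tr[[w]] - or$estimates[[w]]), 3 * or$se[[w]])
  # invariants of the truth object itself
  expect_equal(tr$rr_te, tr$rr_pde * tr$rr_tie, tolerance = 1e-12)
  expect_equal(tr$err_cde + tr$err_intref + tr$err_pie + tr$err_intmed,
               tr$rr_te - 1, tolerance = 1e-12)
})

test_that("event histories are temporally coherent", {
  cfg <- cohort_config(n = 2e4)
  coh <- generate_cohort(cfg, seed = 5)
  for (d in c("cancer", "mi", "depression")) {
    aa <- coh[[paste0("age_dx_", d)]]
    expect_true(all(aa >= 18, na.rm = TRUE))
    expect_true(all(aa <= coh$baseline_age, na.rm = TRUE))
  }
  sm <- coh$ever_smoked == 1
  expect_true(all(!is.na(coh$smoking_init_age[sm])))
  expect_true(all(is.na(coh$smoking_init_age[!sm])))
  both <- sm & !is.na(coh$smoking_quit_age)
  expect_true(all(coh$smoking_init_age[both] <= coh$smoking_quit_age[both]))

  # under-18 cases appear only when requested
  cfg18 <- cohort_config(n = 5e3, timing = list(p_under18_dx = 0.3))
  c18 <- generate_cohort(cfg18, seed = 5)
  expect_gt(sum(c18$age_dx_depression < 18, na.rm = TRUE), 0)

  # injected late initiation is visible in the history but never counts as
  # a pre-diagnosis smoker
  cfgi <- cohort_config(n = 2e4, timing = list(inject_late_initiation = 0.5))
  ci <- generate_cohort(cfgi, seed = 6)
  inj <- ci$ever_smoked == 1 & ci$.m_smoking == 0
  expect_gt(sum(inj), 0)
  m <- derive_smoking_mediator(ci, "depression", "ever_smoking")
  expect_true(all(m[inj] == 0))
})

test_that("cohort CSV and config JSON round-trip", {
  cfg <- cohort_config(n = 200L)
  coh <- generate_cohort(cfg, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, f)
  back <- read_cohort_csv(f)
  expect_false(any(startsWith(names(back), ".")))
  expect_equal(back$smoking_init_age, coh$smoking_init_age)
  expect_equal(back$weight_at_10, coh$weight_at_10)
  expect_equal(back$dx_depression, coh$dx_depression)
  unlink(f)

  g <- tempfile(fileext = ".json")
  write_cohort_config(cfg, g)
  cfg2 <- read_cohort_config(g)
  expect_equal(cfg2$outcomes$mi$lambda0, cfg$outcomes$mi$lambda0)
  expect_equal(mediator_margin(cfg2, "smoking"), mediator_margin(cfg, "smoking"),
               tolerance = 1e-12)
  unlink(g)
})
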