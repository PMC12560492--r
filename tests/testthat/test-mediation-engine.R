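test_that("counterfactual risks integrate the binary mediator exactly", {
  # all-zero coefficients: risk 1 regardless of exposure levels
  p0 <- fake_pair(c(0, 0, 0, 0), c(0, 0))
  for (a in 0:1) for (ap in 0:1)
    expect_equal(counterfactual_mean(p0, a, ap), 1, tolerance = 1e-15)

  # outcome ignoring the mediator: Q independent of the mediator arm
  p1 <- fake_pair(c(-2, 0.4, 0, 0), c(-0.3, 0.8))
  expect_equal(counterfactual_mean(p1, 1, 0), counterfactual_mean(p1, 1, 1),
               tolerance = 1e-15)

  # exact enumeration over m in {0, 1}, written independently of the
  # implementation's closed form
  th <- c(-3, 0.3, 0.5, 0.2); be <- c(-0.4, 0.6)
  pr <- fake_pair(th, be)
  for (a in 0:1) for (ap in 0:1) {
    pm1 <- plogis(be[1] + be[2] * ap)
    enum <- sum(vapply(0:1, function(m)
      (if (m == 1) pm1 else 1 - pm1) *
        exp(th[1] + th[2] * a + th[3] * m + th[4] * a * m), numeric(1)))
    expect_equal(counterfactual_mean(pr, a, ap), enum, tolerance = 1e-12)
  }
})

test_that("closed-form counterfactual risks match the Monte-Carlo oracle", {
  th <- c(-3, 0.3, 0.5, 0.2); be <- c(-0.4, 0.6)
  pr <- fake_pair(th, be)
  or <- monte_carlo_oracle(th, be, n_draws = 2e5, seed = 19)
  expect_lt(abs(counterfactual_mean(pr, 1, 0) - or$estimates[["q10"]]),
            3 * or$se[["q10"]])
  tw <- two_way_decomposition(pr)
  for (w in c("rr_te", "rr_pde", "rr_tie", "pm"))
    expect_lt(abs(tw$estimates[w, "estimate"] - or$estimates[[w]]),
              3 * or$se[[w]])
})

test_that("decomposition identities hold exactly for random coefficient sets", {
  set.seed(202)
  for (i in 1:30) {
    cs <- draw_valid_coefs()
    pr <- fake_pair(cs$theta, cs$beta)
    tw <- two_way_decomposition(pr)$estimates[, "estimate"]
    fw <- four_way_decomposition(pr)
    expect_equal(tw[["rr_te"]], tw[["rr_pde"]] * tw[["rr_tie"]],
                 tolerance = 1e-12)
    expect_equal(sum(fw$estimates[, "estimate"]), tw[["rr_te"]] - 1,
                 tolerance = 1e-12)
    # block mapping: CDE + INT_ref is the direct block, PIE + INT_med the
    # indirect block
    est <- fw$estimates[, "estimate"]
    expect_equal(est[["err_cde"]] + est[["err_intref"]], tw[["rr_pde"]] - 1,
                 tolerance = 1e-12)
    expect_equal(est[["err_pie"]] + est[["err_intmed"]],
                 tw[["rr_pde"]] * (tw[["rr_tie"]] - 1), tolerance = 1e-12)
  }
})

test_that("no-interaction and blocked-path limits are exact", {
  # without a product term the controlled direct effect equals the pure
  # direct effect on the RR scale, so the direct block is pure CDE; the
  # interaction components measure ADDITIVE interaction, which a log-link
  # model retains even at theta3 = 0 - check them against independently
  # derived closed forms
  th <- c(-3, 0.4, 0.6, 0); be <- c(-0.5, 0.7)
  pr <- fake_pair(th, be)
  tw <- two_way_decomposition(pr)$estimates[, "estimate"]
  fw <- four_way_decomposition(pr)$estimates[, "estimate"]
  rr_cde <- exp(th[1] + th[2]) / exp(th[1])
  expect_equal(tw[["rr_pde"]], rr_cde, tolerance = 1e-14)
  p0 <- plogis(be[1]); p1 <- plogis(be[1] + be[2])
  s0 <- (1 - p0) + p0 * exp(th[3])
  expect_equal(fw[["err_intref"]],
               (exp(th[2]) - 1) * p0 * (exp(th[3]) - 1) / s0, tolerance = 1e-12)
  expect_equal(fw[["err_intmed"]],
               (exp(th[2]) - 1) * (exp(th[3]) - 1) * (p1 - p0) / s0,
               tolerance = 1e-12)

  # blocked mediator path: TIE = 1, PM = 0, PIE = INT_med = 0
  pb <- fake_pair(c(-3, 0.4, 0.6, 0.2), c(-0.5, 0))
  twb <- two_way_decomposition(pb)$estimates[, "estimate"]
  expect_equal(twb[["rr_tie"]], 1, tolerance = 1e-15)
  expect_equal(twb[["pm"]], 0, tolerance = 1e-15)
  fwb <- four_way_decomposition(pb)$estimates[, "estimate"]
  expect_equal(fwb[["err_pie"]], 0, tolerance = 1e-15)
  expect_equal(fwb[["err_intmed"]], 0, tolerance = 1e-15)

  # mediator irrelevant to the outcome: TE = PDE = exp(theta1)
  pi <- fake_pair(c(-3, 0.4, 0, 0), c(-0.5, 0.7))
  twi <- two_way_decomposition(pi)$estimates[, "estimate"]
  expect_equal(twi[["rr_tie"]], 1, tolerance = 1e-15)
  expect_equal(twi[["rr_te"]], exp(0.4), tolerance = 1e-12)
})

test_that("linear-outcome mediation follows its closed form", {
  pr <- fake_pair(c(40, -1.5, 2, 0), c(0, 0.5), ofam = "linear")
  res <- mediate_linear_outcome(pr)
  est <- res$estimates[, "estimate"]
  expect_equal(est[["tie"]], 2 * (plogis(0.5) - plogis(0)), tolerance = 1e-12)
  expect_equal(est[["pde"]], -1.5, tolerance = 1e-12)
  expect_equal(est[["pm"]], est[["tie"]] / (est[["pde"]] + est[["tie"]]),
               tolerance = 1e-12)
  # no interaction and blocked path: TIE exactly zero
  p0 <- fake_pair(c(40, -1.5, 2, 0), c(0.3, 0), ofam = "linear")
  expect_equal(mediate_linear_outcome(p0)$estimates["tie", "estimate"], 0,
               tolerance = 1e-15)
})

test_that("the delta method reduces to the Wald interval for a single term", {
  s <- 0.15
  V <- diag(c(0.3, s, 0.2, 0.1, 0.25, 0.2)^2)
  of <- fake_fit(c("(Intercept)" = -2, a = 0.5, m = 0.3, "a:m" = 0.1),
                 "log_poisson", vcov = V[1:4, 1:4])
  mf <- fake_fit(c("(Intercept)" = -0.4, a = 0.6), "logistic",
                 vcov = V[5:6, 5:6])
  mm <- mediation_models(of, mf, "a", "m")
  ci <- delta_ci(function(theta, beta) theta[["a"]], mm, scale = "log")
  expect_equal(unname(ci["estimate"]), exp(0.5), tolerance = 1e-8)
  expect_equal(unname(ci[c("lower", "upper")]),
               exp(0.5 + c(-1, 1) * qnorm(0.975) * s), tolerance = 1e-6)

  # zero covariance: degenerate interval at the point estimate
  ofz <- fake_fit(of$coefficients, "log_poisson", vcov = matrix(0, 4, 4,
                  dimnames = list(names(of$coefficients), names(of$coefficients))))
  mfz <- fake_fit(mf$coefficients, "logistic", vcov = matrix(0, 2, 2,
                  dimnames = list(names(mf$coefficients), names(mf$coefficients))))
  mmz <- mediation_models(ofz, mfz, "a", "m")
  tw <- two_way_decomposition(mmz)
  expect_equal(tw$estimates["pm", "lower"], tw$estimates["pm", "estimate"],
               tolerance = 1e-10)
})

test_that("delta-method and bootstrap standard errors of PM agree", {
  set.seed(77)
  n <- 4000
  a <- rbinom(n, 1, 0.3)
  m <- rbinom(n, 1, plogis(-0.2 + 0.7 * a))
  y <- rbinom(n, 1, exp(-2.5 + 0.35 * a + 0.55 * m + 0.1 * a * m))
  d <- data.frame(a = a, m = m, y = y)
  of <- fit_glm(d, design_spec("y", c("a", "m", "a:m"), "log_poisson"))
  mf <- fit_glm(d, design_spec("m", "a", "logistic"))
  mm <- mediation_models(of, mf, "a", "m", data = d)
  tw_d <- two_way_decomposition(mm, mediation_spec(inference = "delta"))
  tw_b <- two_way_decomposition(mm, mediation_spec(inference = "bootstrap",
                                                   boot_reps = 400,
                                                   boot_seed = 9))
  ratio <- tw_d$estimates["pm", "se"] / tw_b$estimates["pm", "se"]
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
})

test_that("the Monte-Carlo oracle is deterministic and null under null models", {
  o1 <- monte_carlo_oracle(c(-3, 0.3, 0.5, 0.2), c(-0.4, 0.6),
                           n_draws = 1e5, seed = 3)
  o2 <- monte_carlo_oracle(c(-3, 0.3, 0.5, 0.2), c(-0.4, 0.6),
                           n_draws = 1e5, seed = 3)
  expect_identical(o1, o2)

  on <- monte_carlo_oracle(c(log(0.25), 0, 0, 0), c(0, 0),
                           n_draws = 2e5, seed = 4)
  for (w in c("rr_te", "rr_pde", "rr_tie"))
    expect_equal(on$estimates[[w]], 1, tolerance = 1e-12)
  expect_error(monte_carlo_oracle(c(0.5, 0.2, 0, 0), c(0, 0)), "risk exceeds 1")
})
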