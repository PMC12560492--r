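# Shared fixtures, built in code at test time.

# One participant row in the cohort dialect, with benign defaults that pass
# every exclusion rule; override any field via ...
participant <- function(id = 1L, cts = c(1, 1, 1, 5, 5), ever_smoked = 0L,
                        smoking_init_age = NA_real_, smoking_quit_age = NA_real_,
                        weight_at_10 = "regular", weight_kg_18 = 60,
                        weight_kg_30 = 65, weight_kg_50 = NA_real_,
                        baseline_weight_kg = 70, baseline_height_m = 1.70,
                        dx_mi = 0L, age_dx_mi = NA_real_,
                        baseline_age = 55L, sex = "M", center = "C01",
                        education_years = 15L, birth_year = 1959L, ...) {
  row <- data.frame(id = id,
                    cts_emotional_abuse = cts[1], cts_physical_abuse = cts[2],
                    cts_sexual_abuse = cts[3], cts_emotional_neglect = cts[4],
                    cts_physical_neglect = cts[5],
                    ever_smoked = ever_smoked,
                    smoking_init_age = smoking_init_age,
                    smoking_quit_age = smoking_quit_age,
                    weight_at_10 = weight_at_10, weight_kg_18 = weight_kg_18,
                    weight_kg_30 = weight_kg_30, weight_kg_50 = weight_kg_50,
                    baseline_weight_kg = baseline_weight_kg,
                    baseline_height_m = baseline_height_m,
                    dx_cancer = 0L, age_dx_cancer = NA_real_,
                    dx_mi = dx_mi, age_dx_mi = age_dx_mi,
                    dx_stroke = 0L, age_dx_stroke = NA_real_,
                    dx_diabetes = 0L, age_dx_diabetes = NA_real_,
                    dx_copd = 0L, age_dx_copd = NA_real_,
                    dx_anxiety = 0L, age_dx_anxiety = NA_real_,
                    dx_depression = 0L, age_dx_depression = NA_real_,
                    cancer_site = NA_character_,
                    baseline_age = baseline_age, sex = sex, center = center,
                    education_years = education_years, birth_year = birth_year,
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) row[[nm]] <- extra[[nm]]
  row
}

# Ten-record hand fixture exercising the exclusion and timing rules for the
# MI / abuse / smoking analysis:
#   rows 1-2  missing CTS
#   row  3    MI diagnosed at age 15 (excluded: diagnosed before 18)
#   row  4    MI case without an age at diagnosis (excluded)
#   row  5    smoker, init 16, quit 30, MI at 40 (current-smoking variant
#             excludes; ever-smoking codes 1)
#   row  6    smoker, init 45, MI at 40 (initiation after diagnosis -> 0)
#   row  7    never smoker, MI at 40 -> 0
#   row  8    smoker, init 16, MI at 40 -> 1
#   rows 9-10 unexposed controls
hand_cohort <- function() {
  rbind(
    participant(1L, cts = c(NA, 1, 1, 5, 5)),
    participant(2L, cts = c(1, NA, 1, 5, 5)),
    participant(3L, cts = c(3, 1, 1, 5, 5), dx_mi = 1L, age_dx_mi = 15),
    participant(4L, cts = c(3, 1, 1, 5, 5), dx_mi = 1L, age_dx_mi = NA_real_),
    participant(5L, cts = c(3, 1, 1, 5, 5), ever_smoked = 1L,
                smoking_init_age = 16, smoking_quit_age = 30,
                dx_mi = 1L, age_dx_mi = 40),
    participant(6L, cts = c(1, 1, 2, 5, 5), ever_smoked = 1L,
                smoking_init_age = 45, dx_mi = 1L, age_dx_mi = 40),
    participant(7L, cts = c(1, 1, 1, 2, 5), dx_mi = 1L, age_dx_mi = 40),
    participant(8L, cts = c(3, 1, 1, 5, 5), ever_smoked = 1L,
                smoking_init_age = 16, dx_mi = 1L, age_dx_mi = 40),
    participant(9L, cts = c(1, 1, 1, 5, 5)),
    participant(10L, cts = c(1, 1, 1, 5, 5), ever_smoked = 1L,
                smoking_init_age = 20))
}

# Minimal glm_fit stand-in for exercising the closed-form mediation algebra
# with exactly chosen coefficients.
fake_fit <- function(coefs, family, vcov = NULL) {
  p <- length(coefs)
  if (is.null(vcov)) vcov <- diag(1e-4, p)
  dimnames(vcov) <- list(names(coefs), names(coefs))
  structure(list(coefficients = coefs, vcov_model = vcov, vcov_robust = vcov,
                 family = family, n = 1000L, iterations = 1L, converged = TRUE,
                 formula = NULL, term_names = names(coefs), deviance = 0,
                 robust_type = "HC0"),
            class = "glm_fit")
}

# Model pair from fixed effective coefficients theta = (t0, t1, t2, t3),
# beta = (b0, b1), no covariates.
fake_pair <- function(theta, beta, ofam = "log_poisson") {
  of <- fake_fit(stats::setNames(theta, c("(Intercept)", "a", "m", "a:m")), ofam)
  mf <- fake_fit(stats::setNames(beta, c("(Intercept)", "a")), "logistic")
  mediation_models(of, mf, "a", "m")
}

# Single-exposure cohort configuration calibrated so the true proportion
# mediated (abuse -> smoking -> mi) equals pm_target, with an
# exposure-mediator interaction present. Few centers and zero covariate
# coefficients keep the closed-form truth exact and the fits fast.
recovery_config <- function(n, pm_target = 0.30) {
  base <- function(lambda_med) cohort_config(
    n = n,
    exposure = list(p_abuse = 0.1632, p_neglect = 0.02, p_both = 0.02 * 0.1632),
    covariates = list(n_centers = 4L),
    mediators = list(
      smoking = list(gamma0 = 0.0, gamma_abuse = if (pm_target == 0) 0 else 0.55,
                     gamma_neglect = 0),
      overweight = list(gamma_neglect = 0)),
    outcomes = list(mi = list(lambda0 = -3.8, lambda_abuse = 0.25,
                              lambda_neglect = 0, lambda_med = lambda_med,
                              lambda_abuse_med = 0.12,
                              lambda_neglect_med = 0)),
    calibrate = FALSE)
  if (pm_target == 0) return(base(0.6))
  f <- function(lm) true_mediation_effects(base(lm), "mi", "abuse")$pm - pm_target
  lam <- stats::uniroot(f, c(0.05, 1.6), tol = 1e-10)$root
  base(lam)
}

# Estimate the proportion mediated (with CI) for mi/abuse/ever-smoking on a
# generated cohort, via the full derive -> fit -> decompose chain.
estimate_pm <- function(cohort) {
  tab <- build_analysis_table(cohort, "mi", "abuse", "ever_smoking")
  tab$center <- factor(tab$center)
  covs <- c("baseline_age", "female", "education_years", "center")
  of <- fit_glm(tab, design_spec("y", c("a", "m", "a:m", covs), "log_poisson"))
  mf <- fit_glm(tab, design_spec("m", c("a", covs), "logistic"))
  mm <- mediation_models(of, mf, "a", "m", data = tab)
  tw <- two_way_decomposition(mm)
  tw$estimates["pm", ]
}

# Random valid effective coefficient set: outcome intercept <= -2, all other
# coefficients in [-1, 1], rejection-sampled until every risk is <= 1.
draw_valid_coefs <- function() {
  repeat {
    theta <- c(stats::runif(1, -4, -2), stats::runif(3, -1, 1))
    beta <- stats::runif(2, -1, 1)
    sup <- max(outer(0:1, 0:1, function(a, m)
      theta[1] + theta[2] * a + theta[3] * m + theta[4] * a * m))
    if (sup <= 0) return(list(theta = theta, beta = beta))
  }
}
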