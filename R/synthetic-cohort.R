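# Standardisation constants for covariates entering generative models.
# Generative coefficients are expressed on these bounded scales so that
# validity (risk <= 1) can be checked analytically.
.std <- list(age_center = 47, age_scale = 28, edu_center = 15.7, edu_scale = 4.3)

std_age <- function(age) (age - .std$age_center) / .std$age_scale
std_edu <- function(edu) (edu - .std$edu_center) / .std$edu_scale

.diseases <- c("cancer", "mi", "stroke", "diabetes", "copd", "anxiety", "depression")

#' Configuration of the synthetic cohort generator
#'
#' Assembles (and by default calibrates) the generative parameters of a
#' synthetic participant-level cohort: correlated binary childhood
#' exposures (abuse, neglect), covariates, two logistic behavioural
#' mediators (ever smoking, early-onset overweight), seven log-linear
#' binary disease outcomes with exposure-by-mediator interaction, and a
#' timing model that places smoking initiation, overweight milestones and
#' diagnosis ages so the time-sequenced derivation downstream recovers the
#' generative mediator exactly.
#'
#' Default margins reproduce the reference cohort: abuse 16.32%, neglect
#' 14.93% (joint 5.43%), ever smoking 52.80% with marginal risk ratios
#' 1.23 (abuse) and 1.10 (neglect), early-onset overweight 17.09%, and
#' per-disease prevalences between 1.2% and 13.4%.
#'
#' Mediator and outcome covariate coefficients default to zero so that all
#' margins and ground-truth mediation effects are available in closed
#' form; covariates still appear in the data and are adjusted for in
#' estimation.
#'
#' @param n number of participants.
#' @param exposure list: `p_abuse`, `p_neglect`, `p_both` (joint
#'   probability controlling the exposure overlap).
#' @param covariates list: `age_range`, `p_female`, `n_centers`,
#'   `edu_mean`, `edu_sd`, `edu_range`, `baseline_year`.
#' @param mediators named list (`smoking`, `overweight`) of logistic
#'   coefficient sets: `gamma0`, `gamma_abuse`, `gamma_neglect`,
#'   `gamma_cov` (named `age`, `female`, `edu`, standardised scales).
#' @param outcomes named list per disease: `mediator` ("smoking" or
#'   "overweight"), `lambda0`, `lambda_abuse`, `lambda_neglect`,
#'   `lambda_med`, `lambda_abuse_med`, `lambda_neglect_med`, `lambda_cov`,
#'   `dx_age_mean`, `dx_age_sd`.
#' @param timing list: smoking initiation distribution, quit probability,
#'   overweight route probabilities, late-overweight prevalence, and the
#'   test switches `inject_late_initiation` (probability that a
#'   non-smoking case receives an initiation age after diagnosis) and
#'   `p_under18_dx` (probability a case is diagnosed before 18).
#' @param missingness named MCAR rates: `cts`, `smoking`, `weight`,
#'   `disease`, `education`, `dx_age`.
#' @param calibrate recalibrate mediator/outcome intercepts and mediator
#'   exposure coefficients to the `targets` (default TRUE).
#' @param targets calibration targets; see Details. Defaults reproduce the
#'   reference margins above.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n = 10000L,
                          exposure = NULL,
                          covariates = NULL,
                          mediators = NULL,
                          outcomes = NULL,
                          timing = NULL,
                          missingness = NULL,
                          calibrate = TRUE,
                          targets = NULL) {
  def_exposure <- list(p_abuse = 0.1632, p_neglect = 0.1493, p_both = 0.0543)
  def_cov <- list(age_range = c(19L, 75L), p_female = 0.4944, n_centers = 18L,
                  edu_mean = 15.7, edu_sd = 2.2, edu_range = c(8L, 20L),
                  baseline_year = 2014L)
  def_missing <- c(cts = 0, smoking = 0, weight = 0, disease = 0,
                   education = 0, dx_age = 0)
  def_med <- list(
    smoking = list(gamma0 = 0.1, gamma_abuse = 0.5, gamma_neglect = 0.25,
                   gamma_cov = c(age = 0, female = 0, edu = 0)),
    overweight = list(gamma0 = -1.6, gamma_abuse = 0.3, gamma_neglect = 0.15,
                      gamma_cov = c(age = 0, female = 0, edu = 0))
  )
  dx_means <- c(cancer = 48.9, mi = 51.8, stroke = 51.2, diabetes = 51.9,
                copd = 43.1, anxiety = 38.8, depression = 40.0)
  prev <- c(cancer = 0.0388, mi = 0.0133, stroke = 0.0122, diabetes = 0.0397,
            copd = 0.0283, anxiety = 0.0698, depression = 0.1337)
  med_of <- c(cancer = "smoking", mi = "smoking", stroke = "smoking",
              diabetes = "overweight", copd = "smoking", anxiety = "smoking",
              depression = "smoking")
  lam_ab <- c(cancer = 0.10, mi = 0.16, stroke = 0.32, diabetes = 0.25,
              copd = 0.45, anxiety = 0.75, depression = 0.78)
  lam_ng <- c(cancer = 0.05, mi = 0.00, stroke = 0.26, diabetes = 0.07,
              copd = 0.30, anxiety = 0.52, depression = 0.54)
  lam_med <- c(cancer = 0.25, mi = 0.70, stroke = 0.45, diabetes = 0.80,
               copd = 0.85, anxiety = 0.20, depression = 0.15)
  def_out <- lapply(.diseases, function(d) list(
    mediator = med_of[[d]], lambda0 = -4, lambda_abuse = lam_ab[[d]],
    lambda_neglect = lam_ng[[d]], lambda_med = lam_med[[d]],
    lambda_abuse_med = 0.05, lambda_neglect_med = 0,
    lambda_cov = c(age = 0, female = 0, edu = 0),
    dx_age_mean = dx_means[[d]], dx_age_sd = 11))
  names(def_out) <- .diseases
  def_timing <- list(init_age_mean = 17.9, init_age_sd = 2.5,
                     init_age_range = c(10, 30), quit_prob = 0.35,
                     p_age10_only = 0.4546, late_overweight_prob = 0.2684,
                     inject_late_initiation = 0, p_under18_dx = 0)

  merge_list <- function(def, usr) {
    if (is.null(usr)) return(def)
    for (nm in names(usr)) def[[nm]] <- if (is.list(def[[nm]]) && is.list(usr[[nm]]))
      merge_list(def[[nm]], usr[[nm]]) else usr[[nm]]
    def
  }
  miss <- def_missing
  if (!is.null(missingness)) miss[names(missingness)] <- missingness
  cfg <- structure(list(
    n = as.integer(n),
    exposure = merge_list(def_exposure, as.list(exposure)),
    covariates = merge_list(def_cov, as.list(covariates)),
    mediators = merge_list(def_med, mediators),
    outcomes = merge_list(def_out, outcomes),
    timing = merge_list(def_timing, timing),
    missingness = miss), class = "cohort_config")

  if (calibrate) {
    def_targets <- list(
      smoking = list(margin = 0.5280, rr_abuse = 1.23, rr_neglect = 1.10),
      overweight = list(margin = 0.1709, rr_abuse = 1.25, rr_neglect = 1.10),
      prevalence = prev)
    targets <- merge_list(def_targets, targets)
    for (m in c("smoking", "overweight"))
      cfg <- calibrate_mediator(cfg, m, targets[[m]]$margin,
                                targets[[m]]$rr_abuse, targets[[m]]$rr_neglect)
    for (d in names(targets$prevalence))
      cfg <- calibrate_outcome_intercept(cfg, d, targets$prevalence[[d]])
  }
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> n =", x$n, "\n")
  cat("  exposures: abuse", x$exposure$p_abuse, "/ neglect", x$exposure$p_neglect,
      "(joint", x$exposure$p_both, ")\n")
  for (m in names(x$mediators))
    cat("  mediator", m, ": margin", round(mediator_margin(x, m), 4), "\n")
  for (d in names(x$outcomes))
    cat("  disease", d, ": prevalence", round(outcome_prevalence(x, d), 4),
        "<-", x$outcomes[[d]]$mediator, "\n")
  invisible(x)
}

exposure_cell_probs <- function(config) {
  e <- config$exposure
  p11 <- e$p_both; p10 <- e$p_abuse - p11; p01 <- e$p_neglect - p11
  c(p00 = 1 - p10 - p01 - p11, p10 = p10, p01 = p01, p11 = p11)
}

# P(M = 1 | abuse = a, neglect = n) at covariate value zero (std scale)
mediator_prob <- function(config, mediator, ab, ng) {
  g <- config$mediators[[mediator]]
  stats::plogis(g$gamma0 + g$gamma_abuse * ab + g$gamma_neglect * ng)
}

#' Closed-form mediator margin implied by a configuration
#'
#' Marginal prevalence of a mediator over the joint exposure distribution
#' (covariate coefficients must be zero for the closed form to be exact).
#' @param config a [cohort_config()].
#' @param mediator `"smoking"` or `"overweight"`.
#' @export
mediator_margin <- function(config, mediator) {
  pc <- exposure_cell_probs(config)
  sum(pc * c(mediator_prob(config, mediator, 0, 0),
             mediator_prob(config, mediator, 1, 0),
             mediator_prob(config, mediator, 0, 1),
             mediator_prob(config, mediator, 1, 1)))
}

# marginal RR of mediator for one exposure, averaging over the other
mediator_marginal_rr <- function(config, mediator, exposure) {
  pc <- exposure_cell_probs(config)
  if (exposure == "abuse") {
    p1 <- (pc["p10"] * mediator_prob(config, mediator, 1, 0) +
           pc["p11"] * mediator_prob(config, mediator, 1, 1)) / (pc["p10"] + pc["p11"])
    p0 <- (pc["p00"] * mediator_prob(config, mediator, 0, 0) +
           pc["p01"] * mediator_prob(config, mediator, 0, 1)) / (pc["p00"] + pc["p01"])
  } else {
    p1 <- (pc["p01"] * mediator_prob(config, mediator, 0, 1) +
           pc["p11"] * mediator_prob(config, mediator, 1, 1)) / (pc["p01"] + pc["p11"])
    p0 <- (pc["p00"] * mediator_prob(config, mediator, 0, 0) +
           pc["p10"] * mediator_prob(config, mediator, 1, 0)) / (pc["p00"] + pc["p10"])
  }
  unname(p1 / p0)
}

#' Calibrate a mediator model to a target margin and marginal risk ratios
#'
#' Solves the logistic intercept and (optionally) the exposure
#' coefficients of one mediator model so that the implied marginal
#' prevalence and exposure-specific marginal risk ratios equal the
#' targets, by damped fixed-point iteration on the closed-form margins.
#' Requires zero covariate coefficients in the mediator model.
#'
#' @param config a [cohort_config()].
#' @param mediator `"smoking"` or `"overweight"`.
#' @param margin target marginal prevalence.
#' @param rr_abuse,rr_neglect target marginal risk ratios (NULL keeps the
#'   current coefficient).
#' @return the configuration with the mediator model updated.
#' @export
calibrate_mediator <- function(config, mediator, margin, rr_abuse = NULL,
                               rr_neglect = NULL) {
  if (any(config$mediators[[mediator]]$gamma_cov != 0))
    stop("calibration requires zero covariate coefficients in the mediator model")
  for (i in 1:200) {
    g0 <- stats::uniroot(function(g0) {
      config$mediators[[mediator]]$gamma0 <- g0
      mediator_margin(config, mediator) - margin
    }, c(-30, 30), tol = 1e-12)$root
    config$mediators[[mediator]]$gamma0 <- g0
    err <- 0
    if (!is.null(rr_abuse)) {
      ach <- mediator_marginal_rr(config, mediator, "abuse")
      config$mediators[[mediator]]$gamma_abuse <-
        config$mediators[[mediator]]$gamma_abuse + log(rr_abuse / ach)
      err <- max(err, abs(log(rr_abuse / ach)))
    }
    if (!is.null(rr_neglect)) {
      ach <- mediator_marginal_rr(config, mediator, "neglect")
      config$mediators[[mediator]]$gamma_neglect <-
        config$mediators[[mediator]]$gamma_neglect + log(rr_neglect / ach)
      err <- max(err, abs(log(rr_neglect / ach)))
    }
    if (err < 1e-12) break
  }
  config
}

#' Closed-form disease prevalence implied by a configuration
#'
#' Marginal prevalence of one disease over the joint distribution of
#' exposures and its assigned mediator (zero covariate coefficients
#' assumed).
#' @param config a [cohort_config()].
#' @param disease disease identifier.
#' @export
outcome_prevalence <- function(config, disease) {
  o <- config$outcomes[[disease]]
  pc <- exposure_cell_probs(config)
  cells <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  tot <- 0
  for (i in 1:4) {
    ab <- cells[i, 1]; ng <- cells[i, 2]
    pm <- mediator_prob(config, o$mediator, ab, ng)
    for (m in 0:1) {
      lp <- o$lambda0 + o$lambda_abuse * ab + o$lambda_neglect * ng +
        o$lambda_med * m + o$lambda_abuse_med * ab * m +
        o$lambda_neglect_med * ng * m
      tot <- tot + pc[i] * (if (m == 1) pm else 1 - pm) * exp(lp)
    }
  }
  unname(tot)
}

#' Calibrate a disease intercept to a target prevalence
#'
#' The log-linear intercept is additive in the prevalence, so the solve is
#' closed form.
#' @inheritParams outcome_prevalence
#' @param prevalence target marginal prevalence.
#' @export
calibrate_outcome_intercept <- function(config, disease, prevalence) {
  if (any(config$outcomes[[disease]]$lambda_cov != 0))
    stop("calibration requires zero covariate coefficients in the outcome model")
  config$outcomes[[disease]]$lambda0 <- 0
  k <- outcome_prevalence(config, disease)
  config$outcomes[[disease]]$lambda0 <- log(prevalence / k)
  config
}

cov_std_ranges <- function(config) {
  ar <- config$covariates$age_range
  er <- config$covariates$edu_range
  list(age = std_age(ar), female = c(0, 1), edu = std_edu(er))
}

#' Validate a cohort configuration
#'
#' Checks every configuration invariant: probability bounds, nonnegative
#' size, timing distributions confined to ages 10-75, and - for every
#' disease - that the supremum of the log-linear risk over the exposure,
#' mediator and covariate support does not exceed 1, so that Bernoulli
#' draws from the log-link model are always valid. Validation never
#' raises; it returns a character vector of violations (empty when the
#' configuration is valid).
#'
#' @param config a [cohort_config()].
#' @return character vector of violation descriptions, each naming the
#'   offending field and bound.
#' @export
validate_cohort_config <- function(config) {
  v <- character(0)
  chk_prob <- function(x, name) {
    if (!is.numeric(x) || is.na(x) || x < 0 || x > 1)
      sprintf("%s = %s is not a probability in [0, 1]", name, format(x))
    else NA_character_
  }
  if (!is.numeric(config$n) || config$n < 0)
    v <- c(v, "n must be a nonnegative count")
  e <- config$exposure
  v <- c(v, chk_prob(e$p_abuse, "exposure$p_abuse"),
         chk_prob(e$p_neglect, "exposure$p_neglect"),
         chk_prob(e$p_both, "exposure$p_both"),
         chk_prob(config$covariates$p_female, "covariates$p_female"))
  if (is.numeric(e$p_both) && is.numeric(e$p_abuse) && is.numeric(e$p_neglect) &&
      all(c(e$p_both, e$p_abuse, e$p_neglect) >= 0, c(e$p_both, e$p_abuse, e$p_neglect) <= 1)) {
    if (e$p_both > min(e$p_abuse, e$p_neglect) + 1e-12)
      v <- c(v, "exposure$p_both exceeds min(p_abuse, p_neglect)")
    if (e$p_both < e$p_abuse + e$p_neglect - 1 - 1e-12)
      v <- c(v, "exposure$p_both below p_abuse + p_neglect - 1")
  }
  t <- config$timing
  v <- c(v, chk_prob(t$quit_prob, "timing$quit_prob"),
         chk_prob(t$p_age10_only, "timing$p_age10_only"),
         chk_prob(t$late_overweight_prob, "timing$late_overweight_prob"),
         chk_prob(t$inject_late_initiation, "timing$inject_late_initiation"),
         chk_prob(t$p_under18_dx, "timing$p_under18_dx"))
  for (nm in names(config$missingness))
    v <- c(v, chk_prob(config$missingness[[nm]], paste0("missingness$", nm)))
  if (t$init_age_range[1] < 10 || t$init_age_range[2] > 75)
    v <- c(v, "timing$init_age_range must lie within [10, 75]")

  rg <- cov_std_ranges(config)
  sup_cov <- function(coefs) sum(vapply(names(coefs), function(j)
    max(coefs[[j]] * rg[[j]]), numeric(1)))
  for (d in names(config$outcomes)) {
    o <- config$outcomes[[d]]
    sup_lp <- -Inf
    for (ab in 0:1) for (ng in 0:1) for (m in 0:1)
      sup_lp <- max(sup_lp, o$lambda0 + o$lambda_abuse * ab +
                    o$lambda_neglect * ng + o$lambda_med * m +
                    o$lambda_abuse_med * ab * m + o$lambda_neglect_med * ng * m)
    sup_lp <- sup_lp + sup_cov(o$lambda_cov)
    if (sup_lp > 1e-12)
      v <- c(v, sprintf("outcomes$%s: risk exceeds 1 (sup log-risk = %.4f > 0)",
                        d, sup_lp))
    if (o$dx_age_mean < 18 || o$dx_age_mean > 75)
      v <- c(v, sprintf("outcomes$%s$dx_age_mean = %s outside [18, 75]",
                        d, format(o$dx_age_mean)))
  }
  v[!is.na(v)]
}

sample_cts_items <- function(abuse, neglect) {
  n <- length(abuse)
  it <- matrix(0L, n, 5)
  # benign defaults: abuse items low, neglect items (positively phrased) high
  it[, 1] <- sample(1:2, n, replace = TRUE)
  it[, 2] <- sample(1:2, n, replace = TRUE)
  it[, 3] <- 1L
  it[, 4] <- sample(3:5, n, replace = TRUE)
  it[, 5] <- sample(3:5, n, replace = TRUE)
  ia <- which(abuse == 1)
  if (length(ia)) {
    route <- sample(1:3, length(ia), replace = TRUE)
    it[ia[route == 1], 1] <- sample(3:5, sum(route == 1), replace = TRUE)
    it[ia[route == 2], 2] <- sample(3:5, sum(route == 2), replace = TRUE)
    it[ia[route == 3], 3] <- sample(2:5, sum(route == 3), replace = TRUE)
  }
  ineg <- which(neglect == 1)
  if (length(ineg)) {
    route <- sample(1:2, length(ineg), replace = TRUE)
    it[ineg[route == 1], 4] <- sample(1:2, sum(route == 1), replace = TRUE)
    it[ineg[route == 2], 5] <- sample(1:2, sum(route == 2), replace = TRUE)
  }
  colnames(it) <- c("cts_emotional_abuse", "cts_physical_abuse",
                    "cts_sexual_abuse", "cts_emotional_neglect",
                    "cts_physical_neglect")
  it
}

.site_vocabulary <- c("oral_cavity", "pharynx", "esophagus", "stomach",
                      "pancreas", "intestines", "larynx", "lung", "kidney",
                      "urinary_tract", "bladder", "leukemia", "liver",
                      "breast", "cervix", "skin", "thyroid", "brain",
                      "non_hodgkin_lymphoma", "gallbladder", "prostate",
                      "uterus", "ovaries", "testis", "hodgkin_lymphoma")

sample_cancer_site <- function(sex) {
  pw <- c(breast = 0.30, lung = 0.07, intestines = 0.10, skin = 0.16,
          cervix = 0.04, uterus = 0.05, ovaries = 0.04, thyroid = 0.05,
          leukemia = 0.03, kidney = 0.03, stomach = 0.02, pancreas = 0.02,
          brain = 0.02, non_hodgkin_lymphoma = 0.03, liver = 0.01,
          bladder = 0.02, oral_cavity = 0.01)
  pm <- c(prostate = 0.27, lung = 0.12, intestines = 0.12, skin = 0.16,
          bladder = 0.05, kidney = 0.04, leukemia = 0.03, stomach = 0.03,
          pancreas = 0.02, oral_cavity = 0.03, esophagus = 0.02,
          larynx = 0.02, brain = 0.02, non_hodgkin_lymphoma = 0.03,
          liver = 0.02, testis = 0.04)
  out <- character(length(sex))
  iw <- sex == "F"
  if (any(iw)) out[iw] <- sample(names(pw), sum(iw), replace = TRUE, prob = pw)
  if (any(!iw)) out[!iw] <- sample(names(pm), sum(!iw), replace = TRUE, prob = pm)
  out
}

#' Generate a synthetic participant-level cohort
#'
#' Draws a cohort from the generative model described by a validated
#' [cohort_config()]: exposures from their joint distribution, CTS items
#' consistent with the exposure flags, covariates, mediator statuses from
#' the logistic models, disease indicators from the log-linear risks, and
#' - for cases - diagnosis ages, with smoking initiation and overweight
#' milestone histories placed before every reference age so that the
#' downstream time-sequenced derivation recovers the generative mediator
#' exactly (unless the injection switches say otherwise). Regeneration
#' with the same seed is bit-identical.
#'
#' @param config a valid [cohort_config()].
#' @param seed integer RNG seed.
#' @param keep_truth keep the generative flags as dot-prefixed columns
#'   (`.abuse`, `.neglect`, `.m_smoking`, `.m_overweight`); these are
#'   dropped by [write_cohort_csv()].
#' @return data frame with one row per participant; see
#'   [cohort_column_dictionary()] for the column contract.
#' @export
generate_cohort <- function(config, seed = 1L, keep_truth = TRUE) {
  viol <- validate_cohort_config(config)
  if (length(viol)) stop("invalid cohort configuration: ", viol[1])
  set.seed(seed)
  n <- config$n
  if (n == 0L) return(empty_cohort(keep_truth))

  pc <- exposure_cell_probs(config)
  cell <- sample(1:4, n, replace = TRUE, prob = pc)
  abuse <- as.integer(cell %in% c(2, 4))
  neglect <- as.integer(cell %in% c(3, 4))
  cts <- sample_cts_items(abuse, neglect)

  cv <- config$covariates
  age <- sample(cv$age_range[1]:cv$age_range[2], n, replace = TRUE)
  sex <- ifelse(stats::runif(n) < cv$p_female, "F", "M")
  center <- sprintf("C%02d", sample.int(cv$n_centers, n, replace = TRUE))
  edu <- pmin(pmax(round(stats::rnorm(n, cv$edu_mean, cv$edu_sd)),
                   cv$edu_range[1]), cv$edu_range[2])
  birth_year <- cv$baseline_year - age
  cstd <- cbind(age = std_age(age), female = as.numeric(sex == "F"),
                edu = std_edu(edu))

  med <- list()
  for (m in names(config$mediators)) {
    g <- config$mediators[[m]]
    lp <- g$gamma0 + g$gamma_abuse * abuse + g$gamma_neglect * neglect +
      drop(cstd %*% g$gamma_cov[colnames(cstd)])
    med[[m]] <- as.integer(stats::runif(n) < stats::plogis(lp))
  }

  dx <- list(); dxage <- list()
  for (d in names(config$outcomes)) {
    o <- config$outcomes[[d]]
    mm <- med[[o$mediator]]
    lp <- o$lambda0 + o$lambda_abuse * abuse + o$lambda_neglect * neglect +
      o$lambda_med * mm + o$lambda_abuse_med * abuse * mm +
      o$lambda_neglect_med * neglect * mm +
      drop(cstd %*% o$lambda_cov[colnames(cstd)])
    y <- as.integer(stats::runif(n) < exp(lp))
    aa <- rep(NA_real_, n)
    ic <- which(y == 1)
    if (length(ic)) {
      draw <- round(stats::rnorm(length(ic), o$dx_age_mean, o$dx_age_sd))
      aa[ic] <- pmin(pmax(draw, 19), age[ic])
      if (config$timing$p_under18_dx > 0) {
        u18 <- stats::runif(length(ic)) < config$timing$p_under18_dx
        aa[ic][u18] <- sample(10:17, sum(u18), replace = TRUE)
      }
    }
    dx[[d]] <- y; dxage[[d]] <- aa
  }

  # earliest reference age per participant: baseline age and all dx ages
  refmin <- age
  for (d in names(dxage)) refmin <- pmin(refmin, dxage[[d]], na.rm = TRUE)

  tm <- config$timing
  ever <- med$smoking == 1
  init <- rep(NA_real_, n); quit <- rep(NA_real_, n)
  if (any(ever)) {
    draw <- round(stats::rnorm(sum(ever), tm$init_age_mean, tm$init_age_sd))
    draw <- pmin(pmax(draw, tm$init_age_range[1]), tm$init_age_range[2])
    init[ever] <- pmin(draw, refmin[ever] - 1)
    q <- ever & stats::runif(n) < tm$quit_prob & init + 1 <= age
    if (any(q)) {
      span <- age[q] - init[q]
      quit[q] <- init[q] + 1 + floor(stats::runif(sum(q)) * span)
    }
  }
  if (tm$inject_late_initiation > 0) {
    any_case <- Reduce(`|`, lapply(dx, function(y) y == 1))
    cand <- which(!ever & any_case)
    inj <- cand[stats::runif(length(cand)) < tm$inject_late_initiation]
    if (length(inj)) {
      ever[inj] <- TRUE
      init[inj] <- age[inj]   # at the reference age: never "before" any diagnosis
    }
  }

  height <- round(pmin(pmax(stats::rnorm(n, ifelse(sex == "F", 1.65, 1.78),
                                         ifelse(sex == "F", 0.06, 0.07)),
                            1.45), 2.10), 2)
  ow <- med$overweight == 1
  w10 <- character(n); bmi18 <- numeric(n)
  base_no <- sample(c("lower", "regular"), n, replace = TRUE, prob = c(0.2, 0.8))
  w10[] <- base_no
  bmi18[] <- stats::runif(n, 19, 24.8)
  if (any(ow)) {
    via10 <- ow & stats::runif(n) < tm$p_age10_only
    w10[via10] <- "higher"
    via18 <- ow & !via10
    bmi18[via18] <- stats::runif(sum(via18), 25.2, 32)
  }
  late <- stats::runif(n) < tm$late_overweight_prob
  bmi30 <- ifelse(late, stats::runif(n, 25.2, 33), stats::runif(n, 20, 24.8))
  bmi50 <- ifelse(late, stats::runif(n, 25.2, 34), stats::runif(n, 20, 24.8))
  wkg <- function(bmi) round(bmi * height^2, 1)
  weight_kg_18 <- wkg(bmi18)
  weight_kg_30 <- ifelse(age >= 30, wkg(bmi30), NA_real_)
  weight_kg_50 <- ifelse(age >= 50, wkg(bmi50), NA_real_)
  baseline_weight <- wkg(pmin(pmax(stats::rnorm(n, 26, 4), 17), 45))

  site <- rep(NA_character_, n)
  icc <- which(dx$cancer == 1)
  if (length(icc)) site[icc] <- sample_cancer_site(sex[icc])

  out <- data.frame(id = seq_len(n), cts, ever_smoked = as.integer(ever),
                    smoking_init_age = init, smoking_quit_age = quit,
                    weight_at_10 = w10, weight_kg_18 = weight_kg_18,
                    weight_kg_30 = weight_kg_30, weight_kg_50 = weight_kg_50,
                    baseline_weight_kg = baseline_weight,
                    baseline_height_m = height, stringsAsFactors = FALSE)
  for (d in names(dx)) {
    out[[paste0("dx_", d)]] <- dx[[d]]
    out[[paste0("age_dx_", d)]] <- dxage[[d]]
  }
  out$cancer_site <- site
  out$baseline_age <- age
  out$sex <- sex
  out$center <- center
  out$education_years <- edu
  out$birth_year <- birth_year

  ms <- config$missingness
  nafy <- function(cols, rate) {
    if (rate > 0) {
      i <- stats::runif(n) < rate
      out[i, cols] <- NA
    }
    out
  }
  out <- nafy(colnames(cts), ms[["cts"]])
  if (ms[["smoking"]] > 0) {
    i <- stats::runif(n) < ms[["smoking"]]
    out$ever_smoked[i] <- NA
    out$smoking_init_age[i] <- NA
    out$smoking_quit_age[i] <- NA
  }
  out <- nafy(c("weight_at_10", "weight_kg_18"), ms[["weight"]])
  if (ms[["disease"]] > 0)
    for (d in names(dx)) {
      i <- stats::runif(n) < ms[["disease"]]
      out[[paste0("dx_", d)]][i] <- NA
      out[[paste0("age_dx_", d)]][i] <- NA
    }
  out <- nafy("education_years", ms[["education"]])
  if (ms[["dx_age"]] > 0)
    for (d in names(dx)) {
      i <- out[[paste0("dx_", d)]] %in% 1 & stats::runif(n) < ms[["dx_age"]]
      out[[paste0("age_dx_", d)]][i] <- NA
    }

  if (keep_truth) {
    out$.abuse <- abuse; out$.neglect <- neglect
    out$.m_smoking <- med$smoking; out$.m_overweight <- med$overweight
  }
  out
}

empty_cohort <- function(keep_truth = TRUE) {
  cfg <- cohort_config(n = 2L, calibrate = FALSE)
  template <- generate_cohort(cfg, seed = 1L, keep_truth = keep_truth)
  template[0, , drop = FALSE]
}

#' Analytic ground-truth mediation effects of a configuration
#'
#' Applies the package's closed-form decompositions directly to the
#' generative coefficients (logistic mediator, log-linear outcome) of one
#' disease, with exact integration over the binary mediator: the true
#' RR-scale total, pure direct and total indirect effects, the proportion
#' mediated, and the four excess-relative-risk components. Independent of
#' any seed.
#'
#' @param config a valid [cohort_config()].
#' @param disease disease identifier.
#' @param exposure `"abuse"` or `"neglect"`.
#' @param c_cond named standardised covariate values (`age`, `female`,
#'   `edu`), default all zero.
#' @param other value of the non-analysed exposure conditioned on
#'   (default 0).
#' @return object of class `mediation_truth`: list with `rr_te`,
#'   `rr_pde`, `rr_tie`, `pm`, `err_cde`, `err_intref`, `err_pie`,
#'   `err_intmed` and the effective coefficient set used.
#' @export
true_mediation_effects <- function(config, disease,
                                   exposure = c("abuse", "neglect"),
                                   c_cond = c(age = 0, female = 0, edu = 0),
                                   other = 0) {
  exposure <- match.arg(exposure)
  viol <- validate_cohort_config(config)
  if (length(viol)) stop("invalid cohort configuration: ", viol[1])
  if (!disease %in% names(config$outcomes))
    stop("unknown disease identifier: ", disease)
  o <- config$outcomes[[disease]]
  g <- config$mediators[[o$mediator]]
  covn <- c("age", "female", "edu")
  ccov <- c_cond[covn]
  if (exposure == "abuse") {
    t1 <- o$lambda_abuse; t3 <- o$lambda_abuse_med
    t_oth <- o$lambda_neglect; t_oth_m <- o$lambda_neglect_med
    b1 <- g$gamma_abuse; b_oth <- g$gamma_neglect
  } else {
    t1 <- o$lambda_neglect; t3 <- o$lambda_neglect_med
    t_oth <- o$lambda_abuse; t_oth_m <- o$lambda_abuse_med
    b1 <- g$gamma_neglect; b_oth <- g$gamma_abuse
  }
  ec <- list(t0 = o$lambda0 + t_oth * other + sum(o$lambda_cov[covn] * ccov),
             t1 = t1,
             t2 = o$lambda_med + t_oth_m * other,
             t3 = t3,
             b0 = g$gamma0 + b_oth * other + sum(g$gamma_cov[covn] * ccov),
             b1 = b1)
  tw <- two_way_point(ec, 1, 0)
  fw <- four_way_point(ec, 1, 0)
  structure(c(as.list(tw), as.list(fw),
              list(effective = ec, disease = disease, exposure = exposure)),
            class = "mediation_truth")
}

#' @export
print.mediation_truth <- function(x, ...) {
  cat("<mediation_truth>", x$disease, "/", x$exposure, "\n")
  v <- unlist(x[c("rr_te", "rr_pde", "rr_tie", "pm",
                  "err_cde", "err_intref", "err_pie", "err_intmed")])
  print(round(v, 5))
  invisible(x)
}

#' Column dictionary of the cohort CSV dialect
#'
#' @return data frame with one row per column: name, type, units and
#'   allowed codes. Missing values are written as empty fields.
#' @export
cohort_column_dictionary <- function() {
  d <- rbind(
    c("id", "integer", "", "participant identifier"),
    c("cts_emotional_abuse", "integer 1-5", "", "CTS item, 1 = never to 5 = very often"),
    c("cts_physical_abuse", "integer 1-5", "", "CTS item"),
    c("cts_sexual_abuse", "integer 1-5", "", "CTS item"),
    c("cts_emotional_neglect", "integer 1-5", "", "CTS item (positively phrased)"),
    c("cts_physical_neglect", "integer 1-5", "", "CTS item (positively phrased)"),
    c("ever_smoked", "0/1", "", "ever smoked"),
    c("smoking_init_age", "years", "years", "present iff ever_smoked = 1"),
    c("smoking_quit_age", "years", "years", "optional; >= initiation age"),
    c("weight_at_10", "category", "", "lower / regular / higher (vs peers at age 10)"),
    c("weight_kg_18", "numeric", "kg", "recalled weight at age 18"),
    c("weight_kg_30", "numeric", "kg", "recalled weight at age 30 (if reached)"),
    c("weight_kg_50", "numeric", "kg", "recalled weight at age 50 (if reached)"),
    c("baseline_weight_kg", "numeric", "kg", "measured at baseline"),
    c("baseline_height_m", "numeric", "m", "measured at baseline"),
    c("dx_<disease>", "0/1", "", "ever diagnosed; diseases: cancer, mi, stroke, diabetes, copd, anxiety, depression"),
    c("age_dx_<disease>", "years", "years", "age at first diagnosis (cases only)"),
    c("cancer_site", "category", "", "site of first tumour (cancer cases only)"),
    c("baseline_age", "years", "years", "age at baseline examination"),
    c("sex", "category", "", "M / F"),
    c("center", "category", "", "study-center identifier"),
    c("education_years", "years", "years", "years of education"),
    c("birth_year", "calendar year", "", "baseline year minus age"))
  data.frame(column = d[, 1], type = d[, 2], units = d[, 3], codes = d[, 4],
             stringsAsFactors = FALSE)
}

#' Write / read a cohort in the package CSV dialect
#'
#' Missing values are empty fields; generative truth columns (dot-prefixed)
#' are dropped on write.
#' @param cohort cohort data frame.
#' @param path file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  keep <- !startsWith(names(cohort), ".")
  utils::write.csv(cohort[, keep, drop = FALSE], path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = "", colClasses = c(sex = "character",
                                                  weight_at_10 = "character",
                                                  center = "character",
                                                  cancer_site = "character"))
}

#' Write / read a cohort configuration as JSON
#' @param config a [cohort_config()].
#' @param path file path.
#' @export
write_cohort_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (m in names(x$mediators))
    x$mediators[[m]]$gamma_cov <- unlist(x$mediators[[m]]$gamma_cov)
  for (d in names(x$outcomes))
    x$outcomes[[d]]$lambda_cov <- unlist(x$outcomes[[d]]$lambda_cov)
  x$missingness <- unlist(x$missingness)
  structure(x, class = "cohort_config")
}
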