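#' Settings for a mediation decomposition
#'
#' @param a,astar exposed and unexposed exposure levels (defaults 1 and 0).
#' @param mstar reference mediator level for the controlled direct effect
#'   (default 0: never smoker / never overweight).
#' @param c_cond named numeric vector of covariate values at which natural
#'   effects are evaluated, on the basis of the expanded design columns.
#'   `NULL` (default) conditions on the covariate column means of the
#'   outcome-model design matrix.
#' @param level confidence level.
#' @param inference `"delta"` (default) or `"bootstrap"`.
#' @param boot_reps,boot_seed bootstrap replicates and seed (used only for
#'   `inference = "bootstrap"`).
#' @return object of class `mediation_spec`.
#' @export
mediation_spec <- function(a = 1, astar = 0, mstar = 0, c_cond = NULL,
                           level = 0.95, inference = c("delta", "bootstrap"),
                           boot_reps = 500L, boot_seed = 1L) {
  inference <- match.arg(inference)
  if (identical(a, astar)) stop("exposure levels a and a* must differ")
  structure(list(a = a, astar = astar, mstar = mstar, c_cond = c_cond,
                 level = level, inference = inference,
                 boot_reps = as.integer(boot_reps),
                 boot_seed = as.integer(boot_seed)),
            class = "mediation_spec")
}

#' Pair a fitted outcome model with a fitted mediator model
#'
#' Validates that the two fits share the same covariate terms in the same
#' order, locates the exposure, mediator and interaction coefficients, and
#' assembles the joint covariance of the stacked coefficient vector
#' (block-diagonal: sandwich block for the outcome fit, model-based block
#' for the logistic mediator fit, matching separate-sample estimation).
#'
#' @param outcome_fit `glm_fit` for the outcome: intercept, exposure,
#'   mediator, exposure-by-mediator interaction, covariates; family
#'   `log_poisson` (binary outcome) or `linear` (continuous outcome).
#' @param mediator_fit `glm_fit` for the binary mediator: intercept,
#'   exposure, covariates; family `logistic`.
#' @param exposure,mediator column names of the exposure and mediator.
#' @param data optional data frame both models were fitted on; required
#'   for covariate-mean conditioning and for bootstrap inference.
#' @return object of class `mediation_models`.
#' @export
mediation_models <- function(outcome_fit, mediator_fit, exposure, mediator,
                             data = NULL) {
  stopifnot(inherits(outcome_fit, "glm_fit"), inherits(mediator_fit, "glm_fit"))
  if (!outcome_fit$converged || !mediator_fit$converged)
    stop("both fits must have converged")
  if (mediator_fit$family != "logistic")
    stop("the mediator model must be a logistic fit")
  if (!outcome_fit$family %in% c("log_poisson", "linear"))
    stop("the outcome model must be log_poisson or linear")

  on <- names(outcome_fit$coefficients)
  mn <- names(mediator_fit$coefficients)
  int_name <- intersect(c(paste0(exposure, ":", mediator),
                          paste0(mediator, ":", exposure)), on)
  if (!exposure %in% on) stop("exposure term '", exposure, "' absent from outcome fit")
  if (!mediator %in% on) stop("mediator term '", mediator, "' absent from outcome fit")
  if (!exposure %in% mn) stop("exposure term '", exposure, "' absent from mediator fit")
  core_out <- c("(Intercept)", exposure, mediator, int_name)
  cov_out <- setdiff(on, core_out)
  cov_med <- setdiff(mn, c("(Intercept)", exposure))
  if (!identical(cov_out, cov_med))
    stop("covariate terms differ between outcome and mediator fits: [",
         paste(cov_out, collapse = ", "), "] vs [",
         paste(cov_med, collapse = ", "), "]")

  k_out <- length(on); k_med <- length(mn)
  Sigma <- matrix(0, k_out + k_med, k_out + k_med)
  Sigma[seq_len(k_out), seq_len(k_out)] <- outcome_fit$vcov_robust
  Sigma[k_out + seq_len(k_med), k_out + seq_len(k_med)] <- mediator_fit$vcov_model
  dimnames(Sigma) <- list(c(paste0("y.", on), paste0("m.", mn)),
                          c(paste0("y.", on), paste0("m.", mn)))

  structure(list(outcome_fit = outcome_fit, mediator_fit = mediator_fit,
                 exposure = exposure, mediator = mediator,
                 interaction = if (length(int_name)) int_name else NA_character_,
                 covariates = cov_out, Sigma = Sigma, data = data),
            class = "mediation_models")
}

# Collapse the two coefficient vectors and a conditioning covariate vector
# into the effective scalar coefficients (theta0..theta3, beta0, beta1):
# covariate contributions are absorbed into the intercepts.
effective_coefs <- function(theta, beta, models, c_cond) {
  covs <- models$covariates
  if (length(covs)) {
    if (is.null(c_cond) || !all(covs %in% names(c_cond)))
      stop("conditioning covariate values required for: ",
           paste(setdiff(covs, names(c_cond)), collapse = ", "))
    cc <- c_cond[covs]
  } else cc <- numeric(0)
  t0 <- theta[["(Intercept)"]] + sum(theta[covs] * cc)
  t1 <- theta[[models$exposure]]
  t2 <- theta[[models$mediator]]
  t3 <- if (is.na(models$interaction)) 0 else theta[[models$interaction]]
  b0 <- beta[["(Intercept)"]] + sum(beta[covs] * cc)
  b1 <- beta[[models$exposure]]
  list(t0 = t0, t1 = t1, t2 = t2, t3 = t3, b0 = b0, b1 = b1)
}

resolve_c_cond <- function(models, spec) {
  if (!is.null(spec$c_cond)) return(spec$c_cond)
  if (length(models$covariates) == 0L) return(NULL)
  if (is.null(models$data))
    stop("no conditioning covariates given and no data stored in the model pair")
  X <- stats::model.matrix(models$outcome_fit$formula, models$data)
  colMeans(X)[models$covariates]
}

# Closed-form counterfactual risk on effective scalars:
# Q(a, a') = E[Y(a, M(a'))] integrated exactly over the binary mediator.
q_closed <- function(ec, a, aprime) {
  p <- stats::plogis(ec$b0 + ec$b1 * aprime)
  exp(ec$t0 + ec$t1 * a) * ((1 - p) + p * exp(ec$t2 + ec$t3 * a))
}

#' Counterfactual mean risk E[Y(a, M(a'))]
#'
#' Exact integration over the binary mediator: the risk under exposure
#' level `a` with the mediator drawn from its distribution at exposure
#' level `a_prime`, evaluated at the conditioning covariate values. No
#' rare-outcome approximation is used.
#'
#' @param models a [mediation_models()] pair with a binary outcome.
#' @param a exposure level acting on the outcome.
#' @param a_prime exposure level generating the mediator distribution.
#' @param spec a [mediation_spec()].
#' @return nonnegative scalar risk.
#' @export
counterfactual_mean <- function(models, a, a_prime, spec = mediation_spec()) {
  stopifnot(inherits(models, "mediation_models"))
  if (models$outcome_fit$family != "log_poisson")
    stop("counterfactual risks require a binary-outcome (log_poisson) model")
  cc <- resolve_c_cond(models, spec)
  ec <- effective_coefs(models$outcome_fit$coefficients,
                        models$mediator_fit$coefficients, models, cc)
  q_closed(ec, a, a_prime)
}

two_way_point <- function(ec, a, astar) {
  q00 <- q_closed(ec, astar, astar)
  q10 <- q_closed(ec, a, astar)
  q11 <- q_closed(ec, a, a)
  rr_pde <- q10 / q00
  rr_tie <- q11 / q10
  rr_te <- q11 / q00
  pm <- if (abs(rr_te - 1) < .Machine$double.eps * 4) NA_real_
        else rr_pde * (rr_tie - 1) / (rr_te - 1)
  c(rr_te = rr_te, rr_pde = rr_pde, rr_tie = rr_tie, pm = pm)
}

four_way_point <- function(ec, a, astar) {
  r <- function(aa, mm) exp(ec$t0 + ec$t1 * aa + ec$t2 * mm + ec$t3 * aa * mm)
  p <- function(aa) stats::plogis(ec$b0 + ec$b1 * aa)
  D <- q_closed(ec, astar, astar)
  err_cde <- (r(a, 0) - r(astar, 0)) / D
  err_intref <- (q_closed(ec, a, astar) - D) / D - err_cde
  err_pie <- (r(astar, 1) - r(astar, 0)) * (p(a) - p(astar)) / D
  err_intmed <- (q_closed(ec, a, a) - q_closed(ec, a, astar)) / D - err_pie
  c(err_cde = err_cde, err_intref = err_intref,
    err_pie = err_pie, err_intmed = err_intmed)
}

# Delta-method machinery: central finite differences of an effect function
# of the stacked coefficient vector, variance g' Sigma g.
delta_se <- function(effect_fn, x0, Sigma, rel_step = 1e-6) {
  f0 <- effect_fn(x0)
  k <- length(f0)
  G <- matrix(0, length(x0), k)
  for (j in seq_along(x0)) {
    h <- rel_step * max(1, abs(x0[j]))
    xp <- x0; xp[j] <- xp[j] + h
    xm <- x0; xm[j] <- xm[j] - h
    G[j, ] <- (effect_fn(xp) - effect_fn(xm)) / (2 * h)
  }
  se <- sqrt(pmax(colSums(G * (Sigma %*% G)), 0))
  list(estimate = f0, se = se)
}

stacked_coefs <- function(models) {
  c(models$outcome_fit$coefficients, models$mediator_fit$coefficients)
}

split_stacked <- function(x, models) {
  k <- length(models$outcome_fit$coefficients)
  theta <- x[seq_len(k)]
  beta <- x[k + seq_len(length(models$mediator_fit$coefficients))]
  names(theta) <- names(models$outcome_fit$coefficients)
  names(beta) <- names(models$mediator_fit$coefficients)
  list(theta = theta, beta = beta)
}

#' Delta-method confidence interval for a mediation functional
#'
#' Computes the gradient of `effect` with respect to the stacked
#' (outcome, mediator) coefficient vector by central finite differences
#' (relative step 1e-6) and a normal interval with variance
#' \eqn{g^\top \Sigma g}. With `scale = "log"` the effect is treated as a
#' log-scale quantity and the interval is exponentiated (appropriate for
#' risk ratios); `scale = "identity"` gives a plain normal interval
#' (appropriate for the proportion mediated and excess-relative-risk
#' components, whose intervals may legitimately fall outside [0, 1]).
#'
#' @param effect function of `(theta, beta)` (named coefficient vectors)
#'   returning a scalar; for `scale = "log"` it must return the effect on
#'   the log scale.
#' @param models a [mediation_models()] pair.
#' @param level confidence level.
#' @param scale `"identity"` or `"log"`.
#' @return named vector `c(estimate, lower, upper, se)` on the reported
#'   scale.
#' @export
delta_ci <- function(effect, models, level = 0.95, scale = c("identity", "log")) {
  scale <- match.arg(scale)
  x0 <- stacked_coefs(models)
  fn <- function(x) {
    sp <- split_stacked(x, models)
    effect(sp$theta, sp$beta)
  }
  d <- delta_se(fn, x0, models$Sigma)
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- d$estimate; se <- d$se
  if (scale == "log")
    c(estimate = exp(est), lower = exp(est - z * se), upper = exp(est + z * se),
      se = se)
  else
    c(estimate = est, lower = est - z * se, upper = est + z * se, se = se)
}

boot_decompositions <- function(models, spec) {
  if (is.null(models$data))
    stop("bootstrap inference needs the data stored in the model pair")
  data <- models$data
  n <- nrow(data)
  cc <- resolve_c_cond(models, spec)
  out <- matrix(NA_real_, spec$boot_reps, 8,
                dimnames = list(NULL, c("rr_te", "rr_pde", "rr_tie", "pm",
                                        "err_cde", "err_intref", "err_pie",
                                        "err_intmed")))
  set.seed(spec$boot_seed)
  for (b in seq_len(spec$boot_reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    db <- data[idx, , drop = FALSE]
    fo <- tryCatch(fit_glm(db, models$outcome_fit$formula,
                           family = models$outcome_fit$family),
                   error = function(e) NULL)
    fm <- tryCatch(fit_glm(db, models$mediator_fit$formula, family = "logistic"),
                   error = function(e) NULL)
    if (is.null(fo) || is.null(fm)) next
    mb <- mediation_models(fo, fm, models$exposure, models$mediator, data = db)
    ccb <- if (!is.null(spec$c_cond)) spec$c_cond else {
      X <- stats::model.matrix(fo$formula, db)
      colMeans(X)[mb$covariates]
    }
    ec <- effective_coefs(fo$coefficients, fm$coefficients, mb, ccb)
    out[b, 1:4] <- two_way_point(ec, spec$a, spec$astar)
    out[b, 5:8] <- four_way_point(ec, spec$a, spec$astar)
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

perc_ci <- function(x, level) {
  al <- (1 - level) / 2
  stats::quantile(x, c(al, 1 - al), na.rm = TRUE, names = FALSE)
}

#' Two-way mediation decomposition on the risk-ratio scale
#'
#' Decomposes the total effect of a binary exposure on a binary outcome
#' into the pure direct effect and the total indirect effect,
#' \deqn{RR_{TE} = RR_{PDE} \times RR_{TIE},} with the proportion mediated
#' \eqn{PM = RR_{PDE}(RR_{TIE} - 1) / (RR_{TE} - 1)}. Natural effects are
#' evaluated at the conditioning covariate values (covariate means by
#' default). Confidence intervals are delta-method (log scale for risk
#' ratios, identity scale for PM) or bootstrap percentile.
#'
#' @param models a [mediation_models()] pair with binary outcome.
#' @param spec a [mediation_spec()].
#' @return object of class `two_way_result`: rows `rr_te`, `rr_pde`,
#'   `rr_tie`, `pm` with estimate/lower/upper, plus `pm_defined` flag and
#'   the conditioning covariate vector.
#' @export
two_way_decomposition <- function(models, spec = mediation_spec()) {
  stopifnot(inherits(models, "mediation_models"))
  if (models$outcome_fit$family != "log_poisson")
    stop("use mediate_linear_outcome() for linear outcome models")
  cc <- resolve_c_cond(models, spec)
  ec <- effective_coefs(models$outcome_fit$coefficients,
                        models$mediator_fit$coefficients, models, cc)
  pt <- two_way_point(ec, spec$a, spec$astar)

  est <- matrix(NA_real_, 4, 4, dimnames = list(names(pt),
                c("estimate", "lower", "upper", "se")))
  est[, "estimate"] <- pt
  if (spec$inference == "delta") {
    eff <- function(which) function(theta, beta) {
      e <- effective_coefs(theta, beta, models, cc)
      v <- two_way_point(e, spec$a, spec$astar)
      if (which == "pm") v[["pm"]] else log(v[[which]])
    }
    for (w in c("rr_te", "rr_pde", "rr_tie"))
      est[w, ] <- delta_ci(eff(w), models, spec$level, scale = "log")
    if (!is.na(pt[["pm"]]))
      est["pm", ] <- delta_ci(eff("pm"), models, spec$level, scale = "identity")
  } else {
    bt <- boot_decompositions(models, spec)
    for (w in c("rr_te", "rr_pde", "rr_tie", "pm")) {
      ci <- perc_ci(bt[, w], spec$level)
      est[w, c("lower", "upper")] <- ci
      est[w, "se"] <- stats::sd(bt[, w], na.rm = TRUE)
    }
  }
  structure(list(estimates = est, pm_defined = !is.na(pt[["pm"]]),
                 c_cond = cc, spec = spec),
            class = "two_way_result")
}

#' Four-way mediation decomposition on the excess-relative-risk scale
#'
#' Splits the excess relative risk \eqn{RR_{TE} - 1} into four additive
#' components: the controlled direct effect (CDE), the reference
#' interaction (INT_ref), the pure indirect effect (PIE) and the mediated
#' interaction (INT_med). The CDE + INT_ref block equals
#' \eqn{RR_{PDE} - 1}; the PIE + INT_med block equals
#' \eqn{RR_{PDE}(RR_{TIE} - 1)}. Proportions attributable divide each
#' component by \eqn{RR_{TE} - 1}.
#'
#' @inheritParams two_way_decomposition
#' @return object of class `four_way_result`: component estimates with
#'   CIs, proportions attributable, and the total excess relative risk.
#' @export
four_way_decomposition <- function(models, spec = mediation_spec()) {
  stopifnot(inherits(models, "mediation_models"))
  if (models$outcome_fit$family != "log_poisson")
    stop("the four-way decomposition requires a binary-outcome model")
  cc <- resolve_c_cond(models, spec)
  ec <- effective_coefs(models$outcome_fit$coefficients,
                        models$mediator_fit$coefficients, models, cc)
  pt <- four_way_point(ec, spec$a, spec$astar)
  te <- two_way_point(ec, spec$a, spec$astar)[["rr_te"]]

  est <- matrix(NA_real_, 4, 4, dimnames = list(names(pt),
                c("estimate", "lower", "upper", "se")))
  est[, "estimate"] <- pt
  if (spec$inference == "delta") {
    for (w in names(pt)) {
      eff <- local({
        wl <- w
        function(theta, beta) {
          e <- effective_coefs(theta, beta, models, cc)
          four_way_point(e, spec$a, spec$astar)[[wl]]
        }
      })
      est[w, ] <- delta_ci(eff, models, spec$level, scale = "identity")
    }
  } else {
    bt <- boot_decompositions(models, spec)
    for (w in names(pt)) {
      est[w, c("lower", "upper")] <- perc_ci(bt[, w], spec$level)
      est[w, "se"] <- stats::sd(bt[, w], na.rm = TRUE)
    }
  }
  prop <- if (abs(te - 1) < .Machine$double.eps * 4) rep(NA_real_, 4) else pt / (te - 1)
  names(prop) <- paste0("prop_", sub("^err_", "", names(pt)))
  structure(list(estimates = est, proportions = prop, excess_rr = te - 1,
                 c_cond = cc, spec = spec),
            class = "four_way_result")
}

#' @export
print.two_way_result <- function(x, ...) {
  cat("<two_way_result>  RR-scale natural effects (PM on the proportion scale)\n")
  print(round(x$estimates, 4))
  invisible(x)
}

#' @export
print.four_way_result <- function(x, ...) {
  cat("<four_way_result>  excess-RR components (sum = RR_TE - 1 =",
      format(x$excess_rr, digits = 6), ")\n")
  print(round(x$estimates, 4))
  invisible(x)
}

#' Two-way decomposition for a continuous outcome (difference scale)
#'
#' The analogue of [two_way_decomposition()] when the outcome model is
#' linear (e.g. age at diagnosis among affected participants): effects are
#' mean differences,
#' \eqn{Q(a, a') = \phi_0 + \phi_1 a + \phi_4^\top c + (\phi_2 + \phi_3 a) p(a')},
#' with PDE = Q(1,0) - Q(0,0), TIE = Q(1,1) - Q(1,0) and
#' PM = TIE / (PDE + TIE).
#'
#' @inheritParams two_way_decomposition
#' @return object of class `two_way_result` with rows `te`, `pde`, `tie`,
#'   `pm` on the difference scale.
#' @export
mediate_linear_outcome <- function(models, spec = mediation_spec()) {
  stopifnot(inherits(models, "mediation_models"))
  if (models$outcome_fit$family != "linear")
    stop("mediate_linear_outcome() requires a linear outcome fit")
  cc <- resolve_c_cond(models, spec)
  lin_point <- function(theta, beta) {
    e <- effective_coefs(theta, beta, models, cc)
    qlin <- function(a, ap) e$t0 + e$t1 * a + (e$t2 + e$t3 * a) *
      stats::plogis(e$b0 + e$b1 * ap)
    pde <- qlin(spec$a, spec$astar) - qlin(spec$astar, spec$astar)
    tie <- qlin(spec$a, spec$a) - qlin(spec$a, spec$astar)
    te <- pde + tie
    pm <- if (abs(te) < .Machine$double.eps * 4) NA_real_ else tie / te
    c(te = te, pde = pde, tie = tie, pm = pm)
  }
  pt <- lin_point(models$outcome_fit$coefficients,
                  models$mediator_fit$coefficients)
  est <- matrix(NA_real_, 4, 4, dimnames = list(names(pt),
                c("estimate", "lower", "upper", "se")))
  est[, "estimate"] <- pt
  for (w in names(pt)) {
    if (w == "pm" && is.na(pt[["pm"]])) next
    eff <- local({
      wl <- w
      function(theta, beta) lin_point(theta, beta)[[wl]]
    })
    est[w, ] <- delta_ci(eff, models, spec$level, scale = "identity")
  }
  structure(list(estimates = est, pm_defined = !is.na(pt[["pm"]]),
                 c_cond = cc, spec = spec, scale = "difference"),
            class = "two_way_result")
}

#' Monte-Carlo potential-outcome oracle
#'
#' Simulates mediator and outcome potential outcomes directly from the two
#' structural models (logistic mediator, log-linear binary risk) and
#' averages, returning the same estimand set as the closed forms with
#' Monte-Carlo standard errors from batch means. This is the independent
#' check used to validate every closed-form decomposition: it never calls
#' the closed forms.
#'
#' @param theta numeric `c(t0, t1, t2, t3)`: outcome-model intercept,
#'   exposure, mediator and interaction coefficients on the log-risk
#'   scale, covariate contributions already absorbed into `t0`.
#' @param beta numeric `c(b0, b1)`: mediator-model intercept and exposure
#'   coefficient on the logit scale.
#' @param spec a [mediation_spec()] (only `a`, `astar` are used).
#' @param n_draws number of simulated individuals.
#' @param seed RNG seed; identical `(seed, n_draws)` gives identical output.
#' @param n_batches batches for the jackknife standard errors.
#' @return list with `estimates` (named: q11, q10, q00, rr_te, rr_pde,
#'   rr_tie, pm, err_cde, err_intref, err_pie, err_intmed) and matching
#'   `se`. Point estimates are plug-in functionals of the overall
#'   potential-outcome means (so ratio estimands carry no batch-level
#'   Jensen bias); standard errors come from a delete-one-batch jackknife,
#'   which tracks the instability of ratio estimands such as PM when the
#'   total effect is near null.
#' @export
monte_carlo_oracle <- function(theta, beta, spec = mediation_spec(),
                               n_draws = 1e6, seed = 1L, n_batches = 50L) {
  stopifnot(length(theta) == 4, length(beta) == 2)
  a <- spec$a; astar <- spec$astar
  risk <- function(aa, mm) exp(theta[1] + theta[2] * aa + theta[3] * mm +
                               theta[4] * aa * mm)
  rmax <- max(risk(a, 0), risk(a, 1), risk(astar, 0), risk(astar, 1))
  if (rmax > 1 + 1e-12)
    stop("risk exceeds 1 under these coefficients (max ", format(rmax), ")")
  set.seed(seed)
  n <- as.integer(n_draws)
  pstar <- stats::plogis(beta[1] + beta[2] * astar)
  pa <- stats::plogis(beta[1] + beta[2] * a)
  v <- stats::runif(n)
  # monotone coupling: M(a) and M(a*) share the uniform draw
  m_star <- as.numeric(v < pstar)
  m_a <- as.numeric(v < pa)
  u <- stats::runif(n)
  # potential outcomes Y(a, m) for all four (a, m) cells share u
  y_a1 <- as.numeric(u < risk(a, 1)); y_a0 <- as.numeric(u < risk(a, 0))
  y_s1 <- as.numeric(u < risk(astar, 1)); y_s0 <- as.numeric(u < risk(astar, 0))
  y_am <- function(ya1, ya0, m) m * ya1 + (1 - m) * ya0

  # per-draw primitive series; every reported estimand is a smooth
  # function of their means
  dint <- y_a1 - y_s1 - y_a0 + y_s0
  prim <- cbind(q11 = y_am(y_a1, y_a0, m_a),
                q10 = y_am(y_a1, y_a0, m_star),
                q00 = y_am(y_s1, y_s0, m_star),
                cde = y_a0 - y_s0,
                intref = dint * m_star,
                intmed = dint * (m_a - m_star),
                pie = (y_s1 - y_s0) * (m_a - m_star))
  estfun <- function(m) {
    rr_te <- m[["q11"]] / m[["q00"]]
    rr_pde <- m[["q10"]] / m[["q00"]]
    rr_tie <- m[["q11"]] / m[["q10"]]
    c(q11 = m[["q11"]], q10 = m[["q10"]], q00 = m[["q00"]],
      rr_te = rr_te, rr_pde = rr_pde, rr_tie = rr_tie,
      pm = rr_pde * (rr_tie - 1) / (rr_te - 1),
      err_cde = m[["cde"]] / m[["q00"]],
      err_intref = m[["intref"]] / m[["q00"]],
      err_pie = m[["pie"]] / m[["q00"]],
      err_intmed = m[["intmed"]] / m[["q00"]])
  }
  batch <- rep(seq_len(n_batches), length.out = n)
  sums <- rowsum(prim, batch)
  counts <- as.numeric(table(batch))
  tot <- colSums(sums)
  est <- estfun(tot / n)
  # delete-one-batch jackknife
  loo <- vapply(seq_len(n_batches), function(b)
    estfun((tot - sums[b, ]) / (n - counts[b])), numeric(11))
  B <- n_batches
  se <- sqrt((B - 1) / B * rowSums((loo - rowMeans(loo))^2))
  list(estimates = est, se = se, n_draws = n, n_batches = n_batches)
}
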