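#' Describe a regression design
#'
#' Builds a design specification from a response name, a vector of term
#' labels and a model family. Term labels use standard formula syntax
#' (`"a"`, `"a:m"`, `"factor(center)"`); an intercept is always included.
#' Categorical terms are expanded into reference-coded indicators with the
#' first (sorted) level as the reference.
#'
#' @param response name of the response column.
#' @param terms character vector of term labels (may be empty for an
#'   intercept-only model).
#' @param family one of `"log_poisson"` (log link, Poisson working
#'   variance; risk-ratio regression for binary outcomes), `"logistic"`,
#'   or `"linear"`.
#' @return an object of class `design_spec` with elements `formula`,
#'   `family`, `response`, `terms`.
#' @export
design_spec <- function(response, terms = character(), family = c("log_poisson", "logistic", "linear")) {
  family <- match.arg(family)
  stopifnot(is.character(response), length(response) == 1L)
  rhs <- if (length(terms) == 0L) "1" else paste(terms, collapse = " + ")
  f <- stats::as.formula(paste(response, "~", rhs))
  structure(list(formula = f, family = family, response = response, terms = terms),
            class = "design_spec")
}

glm_deviance <- function(y, mu, family) {
  switch(family,
    log_poisson = {
      # Poisson working deviance; y log y defined as 0 at y = 0
      t1 <- ifelse(y > 0, y * log(y / mu), 0)
      2 * sum(t1 - (y - mu))
    },
    logistic = {
      eps <- 1e-12
      -2 * sum(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))
    },
    linear = sum((y - mu)^2)
  )
}

#' Fit a regression model by iteratively reweighted least squares
#'
#' Fits one of the three model families used throughout the pipeline:
#' a log-link GLM with Poisson working variance (modified Poisson
#' regression, yielding risk ratios for binary outcomes), a logistic
#' regression, or ordinary least squares. All families return both the
#' model-based covariance and a heteroscedasticity-robust sandwich
#' covariance (HC0 by default; HC1 applies the n/(n-p) small-sample
#' factor).
#'
#' IRLS starts from zero coefficients with the intercept at the
#' link-transformed response mean, uses step-halving whenever a step
#' increases the deviance, and stops when the score (gradient) norm on the
#' internally standardised design drops below `tol` or after `max_iter`
#' iterations.
#'
#' @param data data frame containing all model columns, no missing values.
#' @param spec a [design_spec()], or a formula (then `family` must be given).
#' @param family model family; ignored when `spec` is a `design_spec`.
#' @param robust_type `"HC0"` (default) or `"HC1"` sandwich flavour.
#' @param tol convergence tolerance on the scaled score norm.
#' @param max_iter maximum IRLS iterations.
#' @return object of class `glm_fit`: coefficients, `vcov_model`,
#'   `vcov_robust`, `family`, `n`, `iterations`, `converged`, `formula`,
#'   term names, deviance.
#' @export
fit_glm <- function(data, spec, family = NULL, robust_type = c("HC0", "HC1"),
                    tol = 1e-8, max_iter = 100L) {
  robust_type <- match.arg(robust_type)
  if (inherits(spec, "design_spec")) {
    formula <- spec$formula
    family <- spec$family
  } else if (inherits(spec, "formula")) {
    formula <- spec
    if (is.null(family)) stop("`family` must be supplied when `spec` is a formula")
    family <- match.arg(family, c("log_poisson", "logistic", "linear"))
  } else stop("`spec` must be a design_spec or a formula")
  if (nrow(data) == 0L) stop("empty analysis table: nothing to fit")

  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(formula, mf)
  n <- nrow(X); p <- ncol(X)

  qrx <- qr(crossprod(X))   # rank of X'X = rank of X; p x p is cheap
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear terms: ", paste(bad, collapse = ", "))
  }

  # standardise non-intercept columns for numerical stability
  scales <- apply(X, 2, stats::sd)
  scales[scales == 0 | colnames(X) == "(Intercept)"] <- 1
  Xs <- sweep(X, 2, scales, "/")

  if (family == "linear") {
    fit <- stats::lm.fit(Xs, y)
    beta_s <- fit$coefficients
    mu <- drop(Xs %*% beta_s)
    r <- y - mu
    XtX <- crossprod(Xs)
    bread <- solve(XtX)
    sigma2 <- sum(r^2) / (n - p)
    vcov_model_s <- sigma2 * bread
    meat <- crossprod(Xs * r)
    vcov_rob_s <- bread %*% meat %*% bread
    if (robust_type == "HC1") vcov_rob_s <- vcov_rob_s * n / (n - p)
    iterations <- 1L; converged <- TRUE
    dev <- sum(r^2)
  } else {
    linkfun <- if (family == "log_poisson") log else stats::qlogis
    invlink <- if (family == "log_poisson") exp else stats::plogis
    beta_s <- rep(0, p)
    ybar <- min(max(mean(y), 1e-8), if (family == "logistic") 1 - 1e-8 else Inf)
    ic <- match("(Intercept)", colnames(X))
    if (!is.na(ic)) beta_s[ic] <- linkfun(ybar)
    eta <- drop(Xs %*% beta_s)
    mu <- invlink(eta)
    dev <- glm_deviance(y, mu, family)
    converged <- FALSE
    iterations <- 0L
    for (it in seq_len(max_iter)) {
      iterations <- it
      w <- if (family == "log_poisson") mu else mu * (1 - mu)
      w <- pmax(w, 1e-12)
      score <- drop(crossprod(Xs, y - mu))
      if (max(abs(score)) < tol) { converged <- TRUE; break }
      info <- crossprod(Xs, Xs * w)
      step <- tryCatch(solve(info, score), error = function(e)
        stop("singular information matrix at iteration ", it,
             " (possible separation): ", conditionMessage(e)))
      fac <- 1
      repeat {
        beta_new <- beta_s + fac * step
        eta_new <- drop(Xs %*% beta_new)
        mu_new <- invlink(pmin(eta_new, 30))
        dev_new <- glm_deviance(y, mu_new, family)
        if (is.finite(dev_new) && dev_new <= dev + 1e-8) break
        fac <- fac / 2
        if (fac < 1e-10) break
      }
      beta_s <- beta_new; eta <- eta_new; mu <- mu_new; dev <- dev_new
      # final score check so a converged last step is recorded as such
      if (max(abs(drop(crossprod(Xs, y - mu)))) < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      hint <- if (family == "logistic" && max(abs(eta)) > 25)
        " (|linear predictor| > 25: likely separation)" else ""
      stop("IRLS did not converge in ", iterations, " iterations; final score norm ",
           format(max(abs(drop(crossprod(Xs, y - mu))))), hint)
    }
    if (family == "logistic" && max(abs(eta)) > 25)
      stop("logistic fit drove fitted probabilities to 0/1 ",
           "(|linear predictor| > 25): separation in the data")
    w <- if (family == "log_poisson") mu else mu * (1 - mu)
    info <- crossprod(Xs, Xs * w)
    bread <- solve(info)
    vcov_model_s <- bread
    r <- y - mu
    meat <- crossprod(Xs * r)
    vcov_rob_s <- bread %*% meat %*% bread
    if (robust_type == "HC1") vcov_rob_s <- vcov_rob_s * n / (n - p)
    if (family == "log_poisson" && all(y %in% c(0, 1)) && any(mu > 1))
      warning("log-Poisson fit on a binary outcome produced ", sum(mu > 1),
              " fitted risks > 1")
  }

  unscale <- function(V) {
    V <- V / tcrossprod(scales)
    (V + t(V)) / 2
  }
  beta <- beta_s / scales
  names(beta) <- colnames(X)
  vm <- unscale(vcov_model_s); dimnames(vm) <- list(colnames(X), colnames(X))
  vr <- unscale(vcov_rob_s); dimnames(vr) <- list(colnames(X), colnames(X))

  structure(list(coefficients = beta, vcov_model = vm, vcov_robust = vr,
                 family = family, n = n, iterations = iterations,
                 converged = converged, formula = formula,
                 term_names = colnames(X), deviance = dev,
                 robust_type = robust_type),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("<glm_fit> family:", x$family, "  n:", x$n,
      "  iterations:", x$iterations, "\n")
  se_m <- sqrt(diag(x$vcov_model)); se_r <- sqrt(diag(x$vcov_robust))
  print(cbind(estimate = x$coefficients, se_model = se_m, se_robust = se_r))
  invisible(x)
}

#' @export
coef.glm_fit <- function(object, ...) object$coefficients

#' @export
vcov.glm_fit <- function(object, robust = TRUE, ...)
  if (robust) object$vcov_robust else object$vcov_model

#' Risk ratio for one model term
#'
#' Exponentiates a coefficient of a log-link Poisson-mean fit into a risk
#' ratio with a Wald confidence interval on the log scale, using the
#' sandwich standard error.
#'
#' @param fit a `glm_fit` with family `log_poisson`.
#' @param term coefficient name.
#' @param level confidence level (default 0.95).
#' @param robust use the sandwich SE (default) or the model-based SE.
#' @return named numeric vector `c(rr, lower, upper, se_log)`.
#' @export
term_rr <- function(fit, term, level = 0.95, robust = TRUE) {
  stopifnot(inherits(fit, "glm_fit"))
  if (fit$family != "log_poisson")
    stop("risk ratios are defined only for log_poisson fits, not ", fit$family)
  if (!term %in% names(fit$coefficients)) stop("term not in fit: ", term)
  b <- fit$coefficients[[term]]
  V <- if (robust) fit$vcov_robust else fit$vcov_model
  se <- sqrt(V[term, term])
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(rr = exp(b), lower = exp(b - z * se), upper = exp(b + z * se), se_log = se)
}

#' Fit-quality diagnostics
#'
#' Recomputes the score vector, the condition number of the weighted
#' information matrix and a leverage summary for a converged fit, for
#' inclusion in run logs.
#'
#' @param fit a `glm_fit`.
#' @param data the data frame the fit was estimated from.
#' @return list with `max_abs_score`, `condition_number`, `leverage`
#'   (min/mean/max of hat diagonals), `n`, `family`.
#' @export
fit_diagnostics <- function(fit, data) {
  stopifnot(inherits(fit, "glm_fit"), fit$converged)
  mf <- stats::model.frame(fit$formula, data, na.action = stats::na.fail)
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(fit$formula, mf)
  eta <- drop(X %*% fit$coefficients)
  mu <- switch(fit$family, log_poisson = exp(eta), logistic = stats::plogis(eta),
               linear = eta)
  w <- switch(fit$family, log_poisson = mu, logistic = mu * (1 - mu),
              linear = rep(1, length(mu)))
  sw <- sqrt(pmax(w, 1e-12))
  Xw <- X * sw
  info <- crossprod(Xw)
  hat <- rowSums((Xw %*% solve(info)) * Xw)
  list(max_abs_score = max(abs(drop(crossprod(X, y - mu)))),
       condition_number = kappa(info, exact = TRUE),
       leverage = c(min = min(hat), mean = mean(hat), max = max(hat)),
       n = fit$n, family = fit$family)
}
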