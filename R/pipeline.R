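#' Configuration of a full mediation study
#'
#' @param diseases outcomes to analyse (default: the nine disease
#'   outcomes including the two cancer sub-classifications).
#' @param exposures childhood exposures to analyse.
#' @param mediators main mediator variants (one per behavioural pathway).
#' @param sensitivity also run the sensitivity variants pairing
#'   `ever_smoking` with `current_smoking` and `early_overweight` with
#'   `early_overweight_18plus`.
#' @param strata subgroup labels from the closed set `all`, `men`,
#'   `women`, `older` (born <= `cohort_cut`), `younger`.
#' @param cohort_cut birth-year cut-off separating the birth cohorts.
#' @param thresholds substantive-effect screen: an RR is substantive iff
#'   RR < `rr_low` or RR > `rr_high` (strict); a linear coefficient iff
#'   |beta| > `beta_abs`.
#' @param ci_level confidence level.
#' @param inference `"delta"` or `"bootstrap"` intervals for the
#'   mediation decompositions.
#' @param min_cases cells with fewer outcome cases (or mediator cases)
#'   are marked not estimable instead of fitted.
#' @param include_age_at_dx also run age-at-diagnosis mediation
#'   (difference scale); disabled by default.
#' @param seed seed recorded in the run manifest.
#' @return object of class `study_config`.
#' @export
study_config <- function(diseases = .analysis_diseases,
                         exposures = c("abuse", "neglect"),
                         mediators = c("ever_smoking", "early_overweight"),
                         sensitivity = FALSE,
                         strata = c("all", "men", "women", "older", "younger"),
                         cohort_cut = 1970L,
                         thresholds = list(rr_low = 0.9, rr_high = 1.1,
                                           beta_abs = 1.0),
                         ci_level = 0.95,
                         inference = c("delta", "bootstrap"),
                         min_cases = 10L,
                         include_age_at_dx = FALSE,
                         seed = 1L) {
  inference <- match.arg(inference)
  stopifnot(all(strata %in% c("all", "men", "women", "older", "younger")),
            all(diseases %in% .analysis_diseases),
            thresholds$rr_low > 0, thresholds$rr_high > 0,
            thresholds$beta_abs > 0)
  variants <- mediators
  if (sensitivity) {
    pair <- c(ever_smoking = "current_smoking",
              early_overweight = "early_overweight_18plus")
    variants <- c(variants, unname(pair[mediators[mediators %in% names(pair)]]))
  }
  structure(list(diseases = diseases, exposures = exposures,
                 mediators = variants, strata = strata,
                 cohort_cut = as.integer(cohort_cut),
                 thresholds = thresholds, ci_level = ci_level,
                 inference = inference, min_cases = as.integer(min_cases),
                 include_age_at_dx = include_age_at_dx,
                 seed = as.integer(seed)),
            class = "study_config")
}

stratum_filter <- function(table, stratum, cohort_cut) {
  switch(stratum,
    all = rep(TRUE, nrow(table)),
    men = table$sex == "M",
    women = table$sex == "F",
    older = table$birth_year <= cohort_cut,
    younger = table$birth_year > cohort_cut)
}

covariate_terms <- function(stratum, n_centers) {
  covs <- c("baseline_age", "education_years")
  if (!stratum %in% c("men", "women")) covs <- c(covs, "female")
  if (n_centers > 1) covs <- c(covs, "center")
  covs
}

not_estimable <- function(why) structure(list(reason = why), class = "not_estimable")

#' Fit the three path regressions of one analysis cell
#'
#' Path A: exposure to mediator; Path B: mediator to outcome; Path C:
#' exposure to outcome (the total effect). Presence outcomes use log-link
#' Poisson-mean regressions with sandwich standard errors, yielding risk
#' ratios; an age-at-diagnosis outcome uses ordinary linear regression for
#' paths B and C on affected participants (path A stays a risk ratio).
#' Degenerate cells (no rows, no cases, constant mediator) return a
#' structured not-estimable result instead of raising.
#'
#' @param table analysis table from [build_analysis_table()].
#' @param outcome_kind `"presence"` or `"age_at_dx"`.
#' @param stratum stratum label, controlling whether sex enters the
#'   covariate set.
#' @param level confidence level.
#' @param min_cases minimum outcome and mediator case counts.
#' @return object of class `path_estimates`: per path, the RR (or beta)
#'   with CI and the underlying `glm_fit`; or `not_estimable`.
#' @export
run_path_models <- function(table, outcome_kind = c("presence", "age_at_dx"),
                            stratum = "all", level = 0.95, min_cases = 10L) {
  outcome_kind <- match.arg(outcome_kind)
  if (nrow(table) == 0L) return(not_estimable("empty table"))
  nc <- length(unique(table$center))
  covs <- covariate_terms(stratum, nc)
  tab <- table
  tab$center <- factor(tab$center)
  binary_y <- outcome_kind == "presence"
  if (binary_y && (sum(tab$y) < min_cases || sum(tab$y == 0) < min_cases))
    return(not_estimable(sprintf("outcome cases %d / non-cases %d below %d",
                                 sum(tab$y), sum(tab$y == 0), min_cases)))
  if (sum(tab$m) < min_cases || sum(tab$m == 0) < min_cases)
    return(not_estimable("mediator nearly constant"))
  if (length(unique(tab$a)) < 2L)
    return(not_estimable("exposure constant"))

  fit_rr <- function(resp, term, data) {
    f <- fit_glm(data, design_spec(resp, c(term, covs), "log_poisson"))
    list(fit = f, est = term_rr(f, term, level = level), kind = "rr")
  }
  res <- tryCatch({
    pa <- fit_rr("m", "a", tab)
    if (binary_y) {
      pb <- fit_rr("y", "m", tab)
      pc <- fit_rr("y", "a", tab)
    } else {
      fb <- fit_glm(tab, design_spec("y", c("m", covs), "linear"))
      fc <- fit_glm(tab, design_spec("y", c("a", covs), "linear"))
      z <- stats::qnorm(1 - (1 - level) / 2)
      lin_est <- function(f, term) {
        b <- f$coefficients[[term]]
        se <- sqrt(f$vcov_model[term, term])
        c(beta = b, lower = b - z * se, upper = b + z * se, se = se)
      }
      pb <- list(fit = fb, est = lin_est(fb, "m"), kind = "beta")
      pc <- list(fit = fc, est = lin_est(fc, "a"), kind = "beta")
    }
    structure(list(path_a = pa, path_b = pb, path_c = pc, n = nrow(tab),
                   n_cases = if (binary_y) sum(tab$y) else nrow(tab),
                   outcome_kind = outcome_kind),
              class = "path_estimates")
  }, error = function(e) not_estimable(conditionMessage(e)))
  res
}

#' Substantive-effect screen
#'
#' Flags each path estimate as substantive - risk ratios when RR < 0.9 or
#' RR > 1.1 (both strict), linear coefficients when |beta| > 1 - and
#' gates interpretation on all three paths being substantive.
#'
#' @param paths a `path_estimates` object.
#' @param thresholds list with `rr_low`, `rr_high`, `beta_abs`.
#' @return list with logical `a`, `b`, `c` flags and `gate` (their
#'   conjunction); all `NA`/`FALSE` for not-estimable input.
#' @export
screen_substantive <- function(paths, thresholds = list(rr_low = 0.9,
                                                        rr_high = 1.1,
                                                        beta_abs = 1.0)) {
  if (inherits(paths, "not_estimable"))
    return(list(a = NA, b = NA, c = NA, gate = FALSE))
  flag1 <- function(p) {
    if (p$kind == "rr") {
      rr <- p$est[["rr"]]
      rr < thresholds$rr_low || rr > thresholds$rr_high
    } else abs(p$est[["beta"]]) > thresholds$beta_abs
  }
  fa <- flag1(paths$path_a); fb <- flag1(paths$path_b); fc <- flag1(paths$path_c)
  list(a = fa, b = fb, c = fc, gate = isTRUE(fa && fb && fc))
}

mediate_cell <- function(tab, stratum, config) {
  nc <- length(unique(tab$center))
  covs <- covariate_terms(stratum, nc)
  tab$center <- factor(tab$center)
  of <- fit_glm(tab, design_spec("y", c("a", "m", "a:m", covs), "log_poisson"))
  mf <- fit_glm(tab, design_spec("m", c("a", covs), "logistic"))
  mm <- mediation_models(of, mf, "a", "m", data = tab)
  sp <- mediation_spec(level = config$ci_level, inference = config$inference,
                       boot_seed = config$seed)
  list(two_way = two_way_decomposition(mm, sp),
       four_way = four_way_decomposition(mm, sp))
}

cell_row <- function(disease, exposure, variant, stratum) {
  data.frame(disease = disease, exposure = exposure, mediator = variant,
             stratum = stratum, n = NA_integer_, n_cases = NA_integer_,
             estimable = FALSE, note = "",
             path_a_rr = NA_real_, path_a_lo = NA_real_, path_a_hi = NA_real_,
             path_b_rr = NA_real_, path_b_lo = NA_real_, path_b_hi = NA_real_,
             path_c_rr = NA_real_, path_c_lo = NA_real_, path_c_hi = NA_real_,
             flag_a = NA, flag_b = NA, flag_c = NA, gate = FALSE,
             rr_pde = NA_real_, rr_pde_lo = NA_real_, rr_pde_hi = NA_real_,
             rr_tie = NA_real_, rr_tie_lo = NA_real_, rr_tie_hi = NA_real_,
             rr_te = NA_real_, rr_te_lo = NA_real_, rr_te_hi = NA_real_,
             pm_pct = NA_real_, pm_lo = NA_real_, pm_hi = NA_real_,
             err_cde = NA_real_, err_intref = NA_real_, err_pie = NA_real_,
             err_intmed = NA_real_,
             excluded_total = NA_integer_, stringsAsFactors = FALSE)
}

#' Run the full mediation study over every analysis cell
#'
#' For every disease x exposure x mediator variant x stratum combination:
#' builds the time-sequenced complete-case analysis table, fits the three
#' path models, applies the substantive-effect screen, and runs the
#' two-way and four-way mediation decompositions with the configured
#' interval method. Cell-level failures are recorded in the row, never
#' aborting the run; the result is deterministic given the cohort and
#' configuration.
#'
#' @param cohort cohort data frame in the package dialect.
#' @param config a [study_config()].
#' @return data frame with one row per cell (class `study_results`);
#'   exclusion ledgers are attached as attribute `"ledgers"`.
#' @export
run_full_study <- function(cohort, config = study_config()) {
  rows <- list(); ledgers <- list()
  for (disease in config$diseases) for (exposure in config$exposures)
    for (variant in config$mediators) {
      full <- build_analysis_table(cohort, disease, exposure, variant,
                                   outcome_kind = "presence")
      key <- paste(disease, exposure, variant, sep = ".")
      ledgers[[key]] <- exclusion_ledger(full)
      for (stratum in config$strata) {
        row <- cell_row(disease, exposure, variant, stratum)
        tab <- full[stratum_filter(full, stratum, config$cohort_cut), ,
                    drop = FALSE]
        row$n <- nrow(tab)
        row$excluded_total <- sum(exclusion_ledger(full)$excluded)
        paths <- run_path_models(tab, "presence", stratum,
                                 level = config$ci_level,
                                 min_cases = config$min_cases)
        if (inherits(paths, "not_estimable")) {
          row$note <- paths$reason
        } else {
          row$n_cases <- paths$n_cases
          row[c("path_a_rr", "path_a_lo", "path_a_hi")] <-
            as.list(paths$path_a$est[c("rr", "lower", "upper")])
          row[c("path_b_rr", "path_b_lo", "path_b_hi")] <-
            as.list(paths$path_b$est[c("rr", "lower", "upper")])
          row[c("path_c_rr", "path_c_lo", "path_c_hi")] <-
            as.list(paths$path_c$est[c("rr", "lower", "upper")])
          fl <- screen_substantive(paths, config$thresholds)
          row$flag_a <- fl$a; row$flag_b <- fl$b; row$flag_c <- fl$c
          row$gate <- fl$gate
          med <- tryCatch(mediate_cell(tab, stratum, config),
                          error = function(e) e)
          if (inherits(med, "error")) {
            row$note <- paste("mediation failed:", conditionMessage(med))
          } else {
            est <- med$two_way$estimates
            row[c("rr_pde", "rr_pde_lo", "rr_pde_hi")] <-
              as.list(est["rr_pde", c("estimate", "lower", "upper")])
            row[c("rr_tie", "rr_tie_lo", "rr_tie_hi")] <-
              as.list(est["rr_tie", c("estimate", "lower", "upper")])
            row[c("rr_te", "rr_te_lo", "rr_te_hi")] <-
              as.list(est["rr_te", c("estimate", "lower", "upper")])
            row[c("pm_pct", "pm_lo", "pm_hi")] <-
              as.list(100 * est["pm", c("estimate", "lower", "upper")])
            row[c("err_cde", "err_intref", "err_pie", "err_intmed")] <-
              as.list(med$four_way$estimates[, "estimate"])
            row$estimable <- TRUE
          }
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  out <- do.call(rbind, rows)
  attr(out, "ledgers") <- ledgers
  attr(out, "config") <- config
  class(out) <- c("study_results", class(out))
  out
}

fmt2 <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))

#' Export a study results table and run manifest
#'
#' Writes one CSV row per analysis cell (risk ratios, natural effects and
#' the proportion mediated formatted to two decimals, excess-RR
#' components to four) and a JSON manifest recording the configuration,
#' seed and software versions. Output is byte-identical across repeated
#' runs with the same cohort and configuration.
#'
#' @param results a `study_results` table from [run_full_study()].
#' @param dir destination directory (created if absent).
#' @param timestamp add a wall-clock timestamp to the manifest (off by
#'   default so that repeated runs produce identical files).
#' @return invisible character vector of the files written.
#' @export
export_report <- function(results, dir, timestamp = FALSE) {
  if (!inherits(results, "study_results") || nrow(results) == 0L)
    stop("results must be a nonempty study_results table")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  config <- attr(results, "config")

  num2 <- c("path_a_rr", "path_a_lo", "path_a_hi", "path_b_rr", "path_b_lo",
            "path_b_hi", "path_c_rr", "path_c_lo", "path_c_hi",
            "rr_pde", "rr_pde_lo", "rr_pde_hi", "rr_tie", "rr_tie_lo",
            "rr_tie_hi", "rr_te", "rr_te_lo", "rr_te_hi",
            "pm_pct", "pm_lo", "pm_hi")
  num4 <- c("err_cde", "err_intref", "err_pie", "err_intmed")
  out <- as.data.frame(results)
  for (cn in num2) out[[cn]] <- fmt2(out[[cn]])
  for (cn in num4) out[[cn]] <- ifelse(is.na(out[[cn]]), "",
                                       sprintf("%.4f", out[[cn]]))
  csv <- file.path(dir, "results.csv")
  utils::write.csv(out, csv, row.names = FALSE, na = "", quote = TRUE)

  ledgers <- attr(results, "ledgers")
  lj <- lapply(ledgers, function(l) list(
    input = l$input, retained = l$retained,
    excluded = stats::setNames(as.list(l$excluded), l$reasons)))
  manifest <- list(
    package = "lcmediate",
    package_version = as.character(utils::packageVersion("lcmediate")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config),
    n_rows = nrow(results),
    n_estimable = sum(results$estimable),
    ledgers = lj)
  if (timestamp) manifest$generated <- format(Sys.time(), tz = "UTC")
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv, mf))
}
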