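.cts_cols <- c("cts_emotional_abuse", "cts_physical_abuse", "cts_sexual_abuse",
               "cts_emotional_neglect", "cts_physical_neglect")

.analysis_diseases <- c("cancer", "cancer_smoking", "cancer_obesity", "mi",
                        "stroke", "diabetes", "copd", "anxiety", "depression")

base_disease <- function(disease) {
  if (disease %in% c("cancer_smoking", "cancer_obesity")) "cancer" else disease
}

#' Score the Childhood Trauma Screener into abuse and neglect exposures
#'
#' Dichotomises the five CTS items (order: emotional abuse, physical
#' abuse, sexual abuse, emotional neglect, physical neglect; each rated
#' 1 = never to 5 = very often) by the moderate/severe cut-offs: >= 3 for
#' emotional and physical abuse, >= 2 for sexual abuse, and <= 2 for the
#' two positively phrased neglect items. Abuse is flagged when any abuse
#' item crosses its cut-off; neglect when either neglect item does.
#'
#' @param items numeric vector of length 5, or an n-by-5 matrix /
#'   data frame with one row per participant.
#' @return data frame with columns `abuse` and `neglect` (0/1; `NA` for
#'   rows with any missing or out-of-range item, which are flagged for
#'   exclusion rather than scored).
#' @export
score_cts <- function(items) {
  if (is.null(dim(items))) items <- matrix(as.numeric(items), nrow = 1)
  items <- as.matrix(items)
  if (ncol(items) != 5) stop("score_cts expects exactly 5 CTS items per row")
  storage.mode(items) <- "numeric"
  bad <- rowSums(is.na(items) | items < 1 | items > 5) > 0
  abuse <- as.integer(items[, 1] >= 3 | items[, 2] >= 3 | items[, 3] >= 2)
  neglect <- as.integer(items[, 4] <= 2 | items[, 5] <= 2)
  abuse[bad] <- NA_integer_
  neglect[bad] <- NA_integer_
  data.frame(abuse = abuse, neglect = neglect)
}

.smoking_sites <- c("oral_cavity", "pharynx", "esophagus", "stomach",
                    "pancreas", "intestines", "larynx", "lung", "kidney",
                    "urinary_tract", "bladder", "leukemia", "liver",
                    "breast", "cervix")
.obesity_sites <- c("oral_cavity", "pharynx", "esophagus", "stomach",
                    "pancreas", "intestines", "larynx", "skin", "kidney",
                    "urinary_tract", "thyroid", "brain",
                    "non_hodgkin_lymphoma", "liver", "gallbladder", "breast",
                    "prostate", "uterus", "ovaries")

#' Classify a cancer site as smoking- and/or obesity-related
#'
#' Applies the two fixed site lists. Breast cancer counts as
#' smoking-related in women only; the obesity-related list carries breast
#' unqualified. Sites in the controlled vocabulary but on neither list
#' (e.g. testis) classify as (0, 0); sites outside the vocabulary also
#' classify as (0, 0) but raise one warning reporting their count.
#'
#' @param site character vector of site terms.
#' @param sex character vector (`"M"`/`"F"`), recycled if length 1.
#' @return data frame with 0/1 columns `smoking_related`,
#'   `obesity_related`.
#' @export
classify_cancer <- function(site, sex) {
  if (length(sex) == 1L) sex <- rep(sex, length(site))
  stopifnot(length(site) == length(sex))
  unknown <- !is.na(site) & !site %in% .site_vocabulary
  if (any(unknown))
    warning(sum(unknown), " cancer site(s) outside the controlled vocabulary",
            " classified as neither smoking- nor obesity-related: ",
            paste(unique(site[unknown]), collapse = ", "))
  smoking <- as.integer(site %in% .smoking_sites &
                        !(site %in% "breast" & sex != "F"))
  obesity <- as.integer(site %in% .obesity_sites)
  smoking[is.na(site)] <- 0L
  obesity[is.na(site)] <- 0L
  data.frame(smoking_related = smoking, obesity_related = obesity)
}

# reference age for mediator timing: age at first diagnosis for cases of
# the disease under analysis, baseline age otherwise
reference_age <- function(data, disease) {
  d <- base_disease(disease)
  y <- data[[paste0("dx_", d)]]
  aa <- data[[paste0("age_dx_", d)]]
  ifelse(!is.na(y) & y == 1 & !is.na(aa), aa, data$baseline_age)
}

#' Disease-specific smoking mediator under the time-sequence rule
#'
#' Never smokers are coded 0. For `ever_smoking`, smokers are coded 1 iff
#' their initiation age is strictly before the reference age (age at first
#' diagnosis for cases, baseline age for non-cases) and 0 otherwise. For
#' `current_smoking`, smokers who quit strictly before the reference age
#' are excluded (comparing never to current smokers); smokers who
#' initiated before and did not quit before the reference age are coded 1.
#' Smokers with a missing initiation age are excluded (missing mediator
#' information).
#'
#' @param data cohort data frame (one or more rows).
#' @param disease disease identifier (sets the reference age).
#' @param variant `"ever_smoking"` or `"current_smoking"`.
#' @return integer vector: 1, 0, or `NA` for excluded rows; the attribute
#'   `"reason"` carries the exclusion reason per excluded row.
#' @export
derive_smoking_mediator <- function(data, disease,
                                    variant = c("ever_smoking", "current_smoking")) {
  variant <- match.arg(variant)
  ref <- reference_age(data, disease)
  ever <- data$ever_smoked
  init <- data$smoking_init_age
  quit <- data$smoking_quit_age
  m <- integer(nrow(data))
  reason <- rep(NA_character_, nrow(data))

  never <- !is.na(ever) & ever == 0
  smoker <- !is.na(ever) & ever == 1
  m[never] <- 0L
  miss <- is.na(ever) | (smoker & is.na(init))
  m[miss] <- NA_integer_
  reason[miss] <- "missing_smoking"

  ok <- smoker & !is.na(init)
  before <- ok & init < ref
  m[ok & !before] <- 0L
  if (variant == "ever_smoking") {
    m[before] <- 1L
  } else {
    quit_before <- before & !is.na(quit) & quit < ref
    m[before & !quit_before] <- 1L
    m[quit_before] <- NA_integer_
    reason[quit_before] <- "quit_before_diagnosis"
  }
  attr(m, "reason") <- reason
  m
}

#' Disease-specific overweight mediator under the time-sequence rule
#'
#' BMI at the milestone ages 18/30/50 is the recalled weight divided by
#' the squared baseline height. `early_overweight` is 1 iff the
#' participant reported a higher weight than peers at age 10 or a BMI
#' >= 25 at age 18, with the qualifying milestone age strictly before the
#' reference age; `early_overweight_18plus` drops the age-10 route;
#' `late_overweight` uses BMI >= 25 at 30 or 50 under the same timing
#' rule. Rows with every weight-history field relevant to the variant
#' missing are excluded; a missing single field simply cannot qualify.
#'
#' @inheritParams derive_smoking_mediator
#' @param variant `"early_overweight"`, `"early_overweight_18plus"` or
#'   `"late_overweight"`.
#' @return integer vector as in [derive_smoking_mediator()].
#' @export
derive_overweight_mediator <- function(data, disease,
                                       variant = c("early_overweight",
                                                   "early_overweight_18plus",
                                                   "late_overweight")) {
  variant <- match.arg(variant)
  ref <- reference_age(data, disease)
  h2 <- data$baseline_height_m^2
  # inclusive threshold, robust to rounding of recorded weights: a weight
  # implying a BMI of exactly 25.0 must qualify
  over <- function(col) !is.na(data[[col]]) & data[[col]] / h2 >= 25 - 1e-9
  q10 <- !is.na(data$weight_at_10) & data$weight_at_10 == "higher" & 10 < ref
  q18 <- over("weight_kg_18") & 18 < ref
  q30 <- over("weight_kg_30") & 30 < ref
  q50 <- over("weight_kg_50") & 50 < ref

  fields <- switch(variant,
    early_overweight = c("weight_at_10", "weight_kg_18"),
    early_overweight_18plus = "weight_kg_18",
    late_overweight = c("weight_kg_30", "weight_kg_50"))
  all_missing <- Reduce(`&`, lapply(fields, function(f) is.na(data[[f]])))

  m <- switch(variant,
    early_overweight = as.integer(q10 | q18),
    early_overweight_18plus = as.integer(q18),
    late_overweight = as.integer(q30 | q50))
  reason <- rep(NA_character_, nrow(data))
  m[all_missing] <- NA_integer_
  reason[all_missing] <- "missing_weight_history"
  attr(m, "reason") <- reason
  m
}

mediator_kind <- function(variant) {
  if (variant %in% c("ever_smoking", "current_smoking")) "smoking" else "overweight"
}

derive_mediator <- function(data, disease, variant) {
  if (mediator_kind(variant) == "smoking")
    derive_smoking_mediator(data, disease, variant)
  else derive_overweight_mediator(data, disease, variant)
}

#' Assemble a disease-specific complete-case analysis table
#'
#' Builds the rectangle one regression consumes: exposure (from CTS
#' scoring), time-sequenced mediator, outcome (disease presence or age at
#' first diagnosis), and covariates, removing excluded rows and
#' accounting for every removal in an exclusion ledger. Each excluded row
#' is attributed to exactly one reason, assessed in a fixed order:
#' missing CTS, missing smoking history, missing weight history, missing
#' disease history, missing education, then missing age at diagnosis and
#' diagnosis before age 18 among cases, then variant-specific rules
#' (smokers who quit before the diagnosis under `current_smoking`).
#' Cancer sub-outcomes (`cancer_smoking`, `cancer_obesity`) are built by
#' classifying the first tumour site; cancer cases whose site falls
#' outside the class count as non-cases of the sub-outcome.
#'
#' @param cohort cohort data frame in the package dialect.
#' @param disease one of cancer, cancer_smoking, cancer_obesity, mi,
#'   stroke, diabetes, copd, anxiety, depression.
#' @param exposure `"abuse"` or `"neglect"`.
#' @param variant a mediator variant name.
#' @param outcome_kind `"presence"` (binary) or `"age_at_dx"` (linear,
#'   affected participants only).
#' @return data frame with columns `a`, `m`, `y`, `baseline_age`,
#'   `female`, `education_years`, `center`, `sex`, `birth_year`; the
#'   exclusion ledger is attached as attribute `"ledger"` (class
#'   `exclusion_ledger`) and retrievable with [exclusion_ledger()].
#' @export
build_analysis_table <- function(cohort, disease,
                                 exposure = c("abuse", "neglect"),
                                 variant = "ever_smoking",
                                 outcome_kind = c("presence", "age_at_dx")) {
  exposure <- match.arg(exposure)
  outcome_kind <- match.arg(outcome_kind)
  if (!disease %in% .analysis_diseases)
    stop("unknown disease identifier: ", disease)
  if (nrow(cohort) == 0L) stop("empty cohort")
  d <- base_disease(disease)
  n <- nrow(cohort)

  sc <- score_cts(cohort[, .cts_cols])
  a <- sc[[exposure]]
  ycol <- cohort[[paste0("dx_", d)]]
  aa <- cohort[[paste0("age_dx_", d)]]

  reason <- rep(NA_character_, n)
  assign_reason <- function(cond, label) {
    hit <- is.na(reason) & cond
    reason[hit] <<- label
  }
  assign_reason(is.na(sc$abuse), "missing_cts")
  assign_reason(is.na(cohort$ever_smoked) |
                  (cohort$ever_smoked %in% 1 & is.na(cohort$smoking_init_age)),
                "missing_smoking")
  assign_reason(is.na(cohort$weight_at_10) & is.na(cohort$weight_kg_18),
                "missing_weight_history")
  assign_reason(is.na(ycol), "missing_disease_history")
  assign_reason(is.na(cohort$education_years), "missing_education")
  is_case <- !is.na(ycol) & ycol == 1
  assign_reason(is_case & is.na(aa), "missing_dx_age")
  assign_reason(is_case & !is.na(aa) & aa < 18, "diagnosed_before_18")

  m <- derive_mediator(cohort, disease, variant)
  mreason <- attr(m, "reason")
  assign_reason(is.na(m) & !is.na(mreason), "variant_exclusion")
  # refine the catch-all with the mediator's own labels
  vi <- which(reason == "variant_exclusion")
  reason[vi] <- mreason[vi]

  if (disease %in% c("cancer_smoking", "cancer_obesity")) {
    cls <- classify_cancer(cohort$cancer_site, cohort$sex)
    inclass <- if (disease == "cancer_smoking") cls$smoking_related else
      cls$obesity_related
    y <- as.integer(is_case & inclass == 1)
  } else {
    y <- as.integer(is_case)
  }

  keep <- is.na(reason)
  if (outcome_kind == "age_at_dx") keep <- keep & y == 1

  out <- data.frame(a = a[keep], m = m[keep],
                    y = if (outcome_kind == "presence") y[keep] else aa[keep],
                    baseline_age = cohort$baseline_age[keep],
                    female = as.numeric(cohort$sex[keep] == "F"),
                    education_years = cohort$education_years[keep],
                    center = cohort$center[keep],
                    sex = cohort$sex[keep],
                    birth_year = cohort$birth_year[keep],
                    stringsAsFactors = FALSE)

  counts <- table(factor(reason[!is.na(reason)],
                         levels = c("missing_cts", "missing_smoking",
                                    "missing_weight_history",
                                    "missing_disease_history",
                                    "missing_education", "missing_dx_age",
                                    "diagnosed_before_18",
                                    "quit_before_diagnosis")))
  ledger <- structure(list(input = n,
                           retained = if (outcome_kind == "presence") nrow(out)
                                      else sum(is.na(reason)),
                           excluded = as.integer(counts),
                           reasons = names(counts),
                           disease = disease, exposure = exposure,
                           variant = variant, outcome_kind = outcome_kind),
                      class = "exclusion_ledger")
  attr(out, "ledger") <- ledger
  out
}

#' Exclusion ledger of an analysis table
#'
#' @param table an analysis table from [build_analysis_table()].
#' @return the `exclusion_ledger` attached to the table.
#' @export
exclusion_ledger <- function(table) attr(table, "ledger")

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat("<exclusion_ledger>", x$disease, "/", x$exposure, "/", x$variant, "\n")
  cat("  input:", x$input, " retained:", x$retained, "\n")
  nz <- x$excluded > 0
  if (any(nz))
    for (i in which(nz)) cat("  ", x$reasons[i], ":", x$excluded[i], "\n")
  else cat("   no exclusions\n")
  invisible(x)
}

#' Serialise an exclusion ledger to JSON
#' @param ledger an `exclusion_ledger`.
#' @param path file path.
#' @export
write_exclusion_ledger <- function(ledger, path) {
  x <- list(input = ledger$input, retained = ledger$retained,
            excluded = stats::setNames(as.list(ledger$excluded), ledger$reasons),
            disease = ledger$disease, exposure = ledger$exposure,
            variant = ledger$variant, outcome_kind = ledger$outcome_kind)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
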