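test_that("CTS items dichotomise by the moderate/severe cut-offs", {
  cases <- list(
    list(items = c(3, 1, 1, 5, 5), abuse = 1L, neglect = 0L),  # emotional abuse >= 3
    list(items = c(1, 1, 2, 5, 5), abuse = 1L, neglect = 0L),  # sexual abuse >= 2
    list(items = c(1, 1, 1, 2, 5), abuse = 0L, neglect = 1L),  # neglect <= 2 (positively phrased)
    list(items = c(1, 1, 1, 5, 5), abuse = 0L, neglect = 0L),
    list(items = c(1, 3, 1, 5, 1), abuse = 1L, neglect = 1L),
    list(items = c(2, 2, 1, 3, 3), abuse = 0L, neglect = 0L))
  for (cs in cases) {
    sc <- score_cts(cs$items)
    expect_identical(sc$abuse, cs$abuse)
    expect_identical(sc$neglect, cs$neglect)
  }
  # missing or out-of-range items flag the record instead of scoring it
  expect_true(is.na(score_cts(c(NA, 1, 1, 5, 5))$abuse))
  expect_true(is.na(score_cts(c(1, 1, 6, 5, 5))$neglect))
  m <- score_cts(rbind(c(3, 1, 1, 5, 5), c(1, 1, 1, 5, 5)))
  expect_identical(m$abuse, c(1L, 0L))
})

test_that("cancer sites classify by the smoking and obesity lists", {
  expect_identical(unlist(classify_cancer("lung", "M")), c(smoking_related = 1L, obesity_related = 0L))
  # breast is smoking-related in women only; the obesity list is unqualified
  expect_identical(unlist(classify_cancer("breast", "M")), c(smoking_related = 0L, obesity_related = 1L))
  expect_identical(unlist(classify_cancer("breast", "F")), c(smoking_related = 1L, obesity_related = 1L))
  expect_identical(unlist(classify_cancer("skin", "F")), c(smoking_related = 0L, obesity_related = 1L))
  expect_identical(unlist(classify_cancer("cervix", "F")), c(smoking_related = 1L, obesity_related = 0L))
  # in-vocabulary site on neither list is silently (0, 0)
  expect_warning(t0 <- classify_cancer("testis", "M"), regexp = NA)
  expect_identical(unlist(t0), c(smoking_related = 0L, obesity_related = 0L))
  # out-of-vocabulary site warns once with a count
  expect_warning(u <- classify_cancer(c("lung", "xyz"), c("M", "M")),
                 "outside the controlled vocabulary")
  expect_identical(u$smoking_related, c(1L, 0L))
})

test_that("the smoking mediator obeys the time-sequence rules", {
  rec <- function(...) participant(...)
  ever <- function(r) derive_smoking_mediator(r, "mi", "ever_smoking")
  curr <- function(r) derive_smoking_mediator(r, "mi", "current_smoking")

  smoker <- rec(ever_smoked = 1L, smoking_init_age = 16, dx_mi = 1L, age_dx_mi = 40)
  expect_identical(as.integer(ever(smoker)), 1L)
  expect_identical(as.integer(curr(smoker)), 1L)

  quitter <- rec(ever_smoked = 1L, smoking_init_age = 16, smoking_quit_age = 30,
                 dx_mi = 1L, age_dx_mi = 40)
  expect_identical(as.integer(ever(quitter)), 1L)
  mq <- curr(quitter)
  expect_true(is.na(mq))
  expect_identical(attr(mq, "reason"), "quit_before_diagnosis")
  # quitting at or after the diagnosis keeps the current-smoker code
  late_quit <- rec(ever_smoked = 1L, smoking_init_age = 16,
                   smoking_quit_age = 40, dx_mi = 1L, age_dx_mi = 40)
  expect_identical(as.integer(curr(late_quit)), 1L)

  # initiation after (or at) the diagnosis cannot mediate
  late <- rec(ever_smoked = 1L, smoking_init_age = 45, dx_mi = 1L, age_dx_mi = 40)
  expect_identical(as.integer(ever(late)), 0L)
  at <- rec(ever_smoked = 1L, smoking_init_age = 40, dx_mi = 1L, age_dx_mi = 40)
  expect_identical(as.integer(ever(at)), 0L)

  expect_identical(as.integer(ever(rec())), 0L)  # never smoker
  # non-cases use the baseline age as reference
  nc <- rec(ever_smoked = 1L, smoking_init_age = 20, baseline_age = 55L)
  expect_identical(as.integer(ever(nc)), 1L)
  miss <- rec(ever_smoked = 1L)
  expect_identical(attr(ever(miss), "reason"), "missing_smoking")
})

test_that("the overweight mediator obeys the milestone and BMI rules", {
  h <- 1.70
  ow <- function(r, v) derive_overweight_mediator(r, "mi", v)
  r10 <- participant(weight_at_10 = "higher", weight_kg_18 = 22 * h^2,
                     dx_mi = 1L, age_dx_mi = 35)
  expect_identical(as.integer(ow(r10, "early_overweight")), 1L)
  # the age-10 route alone never qualifies under the 18+ variant
  expect_identical(as.integer(ow(r10, "early_overweight_18plus")), 0L)

  # BMI threshold is inclusive at exactly 25
  r25 <- participant(weight_kg_18 = 25 * h^2)
  expect_identical(as.integer(ow(r25, "early_overweight")), 1L)
  expect_identical(as.integer(ow(r25, "early_overweight_18plus")), 1L)
  r249 <- participant(weight_kg_18 = 24.9 * h^2)
  expect_identical(as.integer(ow(r249, "early_overweight")), 0L)

  # milestone age must fall strictly before the reference age
  r30 <- participant(weight_kg_30 = 27 * h^2, dx_mi = 1L, age_dx_mi = 25)
  expect_identical(as.integer(ow(r30, "late_overweight")), 0L)
  r30b <- participant(weight_kg_30 = 27 * h^2, dx_mi = 1L, age_dx_mi = 45)
  expect_identical(as.integer(ow(r30b, "late_overweight")), 1L)
  # diagnosis exactly at 18 blocks the BMI-18 route
  r18 <- participant(weight_kg_18 = 27 * h^2, dx_mi = 1L, age_dx_mi = 18)
  expect_identical(as.integer(ow(r18, "early_overweight")), 0L)

  miss <- participant(weight_at_10 = NA_character_, weight_kg_18 = NA_real_)
  expect_identical(attr(ow(miss, "early_overweight"), "reason"),
                   "missing_weight_history")
})

test_that("the hand fixture yields the exact ledger and mediator codes", {
  coh <- hand_cohort()
  tab <- build_analysis_table(coh, "mi", "abuse", "ever_smoking")
  led <- exclusion_ledger(tab)
  expect_equal(nrow(tab), 6L)
  expect_equal(led$input, 10L)
  expect_equal(led$retained, 6L)
  exc <- setNames(led$excluded, led$reasons)
  expect_equal(unname(exc["missing_cts"]), 2L)
  expect_equal(unname(exc["diagnosed_before_18"]), 1L)
  expect_equal(unname(exc["missing_dx_age"]), 1L)
  expect_equal(sum(exc), 4L)
  expect_equal(led$input, led$retained + sum(exc))
  # ever-smoking codes: quitter 1, late initiator 0, never smoker 0,
  # pre-diagnosis smoker 1, controls 0/1
  expect_identical(tab$m, c(1L, 0L, 0L, 1L, 0L, 1L))
  expect_identical(tab$a, c(1L, 1L, 0L, 1L, 0L, 0L))
  expect_identical(tab$y, c(1L, 1L, 1L, 1L, 0L, 0L))

  # the current-smoking variant additionally excludes the quitter
  tabc <- build_analysis_table(coh, "mi", "abuse", "current_smoking")
  ledc <- exclusion_ledger(tabc)
  excc <- setNames(ledc$excluded, ledc$reasons)
  expect_equal(unname(excc["quit_before_diagnosis"]), 1L)
  expect_equal(nrow(tabc), 5L)

  # a fixture without exclusions retains everything
  clean <- coh[7:10, ]
  tab0 <- build_analysis_table(clean, "mi", "abuse", "ever_smoking")
  expect_equal(nrow(tab0), 4L)
  expect_equal(sum(exclusion_ledger(tab0)$excluded), 0L)

  # affected-only table for age-at-diagnosis outcomes
  taba <- build_analysis_table(coh, "mi", "abuse", "ever_smoking",
                               outcome_kind = "age_at_dx")
  expect_equal(nrow(taba), 4L)
  expect_true(all(taba$y >= 18))
})

test_that("ledger conservation holds under random missingness", {
  cfg <- cohort_config(n = 4000L,
                       missingness = c(cts = 0.1, smoking = 0.05, weight = 0.08,
                                       disease = 0.02, education = 0.05,
                                       dx_age = 0.1))
  coh <- generate_cohort(cfg, seed = 21)
  for (d in c("mi", "cancer_smoking", "depression"))
    for (v in c("ever_smoking", "current_smoking", "early_overweight")) {
      tab <- build_analysis_table(coh, d, "abuse", v)
      led <- exclusion_ledger(tab)
      expect_equal(led$input, led$retained + sum(led$excluded))
      expect_equal(led$retained, nrow(tab))
      expect_false(anyNA(tab[, c("a", "m", "y", "baseline_age", "female",
                                 "education_years")]))
    }
})

test_that("derived mediators recover the generative flags exactly", {
  cfg <- cohort_config(n = 2e4)
  coh <- generate_cohort(cfg, seed = 33)
  for (d in c("mi", "depression")) {
    m <- derive_smoking_mediator(coh, d, "ever_smoking")
    expect_identical(as.integer(m), coh$.m_smoking)
  }
  ow <- derive_overweight_mediator(coh, "diabetes", "early_overweight")
  expect_identical(as.integer(ow), coh$.m_overweight)
  # derivation is deterministic: rebuilding gives the identical table
  t1 <- build_analysis_table(coh, "mi", "abuse", "ever_smoking")
  t2 <- build_analysis_table(coh, "mi", "abuse", "ever_smoking")
  expect_identical(t1, t2)
})

test_that("cancer sub-outcomes are classified from the tumour site", {
  cfg <- cohort_config(n = 3e4)
  coh <- generate_cohort(cfg, seed = 44)
  ts <- build_analysis_table(coh, "cancer_smoking", "abuse", "ever_smoking")
  to <- build_analysis_table(coh, "cancer_obesity", "abuse", "ever_smoking")
  tc <- build_analysis_table(coh, "cancer", "abuse", "ever_smoking")
  # sub-outcomes keep the full denominator but fewer cases
  expect_equal(nrow(ts), nrow(tc))
  expect_lt(sum(ts$y), sum(tc$y))
  expect_lt(sum(to$y), sum(tc$y))
  expect_gt(sum(ts$y), 0)
  cls <- classify_cancer(coh$cancer_site, coh$sex)
  expect_equal(sum(ts$y), sum(cls$smoking_related == 1 & coh$dx_cancer == 1 &
                              !is.na(coh$age_dx_cancer) & coh$age_dx_cancer >= 18))
})
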