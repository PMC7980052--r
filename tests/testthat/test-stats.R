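test_that("prevalence percents and shares reproduce printed-table rounding", {
  cohort <- make_printed_cohort()
  pt <- prevalence_table(cohort)
  expect_identical(unname(pt$percents),
                   c(21.4, 43.6, 30.4, 3.0, 1.7))
  expect_identical(pt$classified_total, 270276L)
  expect_identical(pt$unclassified_count, 13992L)
  expect_identical(pt$heightened_risk_percent, 4.7)
  expect_identical(pt$documentation_rate, 40.6)
})

test_that("prevalence handles tiny and empty cohorts", {
  one <- data.frame(patient_id = 1, documented = TRUE, category = "LIGHT")
  pt <- prevalence_table(one)
  expect_identical(unname(pt$percents), c(0, 100, 0, 0, 0))
  none <- data.frame(patient_id = 1, documented = TRUE,
                     category = "UNKNOWN")
  expect_error(prevalence_table(none), "no classified")
})

test_that("prevalence is invariant under row permutation", {
  set.seed(23)
  cohort <- data.frame(
    patient_id = 1:500,
    documented = TRUE,
    category = sample(alcohol_categories(), 500, TRUE))
  a <- prevalence_table(cohort)
  b <- prevalence_table(cohort[sample(500), ])
  expect_identical(a, b)
})

test_that("bivariate comparison: null case, printed proportions, t branch", {
  # identical proportions in both groups -> chi-square 0, p = 1
  cohort <- data.frame(documented = rep(c(TRUE, FALSE), each = 100),
                       flag = rep(c(TRUE, FALSE), 100))
  bv <- bivariate_compare(cohort, "flag")
  expect_equal(bv$statistic, 0)
  expect_equal(bv$p, 1)
  # published male shares: 43.7% documented vs 42.4% undocumented
  bc <- bivariate_compare(make_printed_cohort(), "male")
  expect_identical(round_half_up(100 * bc$documented$estimate, 1), 43.7)
  expect_identical(round_half_up(100 * bc$undocumented$estimate, 1), 42.4)
  expect_lt(bc$p, 1e-4)
  # numeric branch uses Welch's t
  set.seed(9)
  cont <- data.frame(documented = rep(c(TRUE, FALSE), each = 200),
                     age = c(rnorm(200, 52), rnorm(200, 50)))
  bt <- bivariate_compare(cont, "age")
  expect_identical(bt$type, "t")
  expect_lt(bt$p, 0.01)
  # zero cell switches to the exact test
  zc <- data.frame(documented = c(TRUE, TRUE, FALSE, FALSE),
                   flag = c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(bivariate_compare(zc, "flag")$type, "fisher")
})

test_that("bivariate chi-square holds its type-I error under the null", {
  set.seed(55)
  reps <- 400
  rejected <- 0
  for (r in seq_len(reps)) {
    cohort <- data.frame(documented = rbinom(120, 1, 0.4) == 1,
                         flag = rbinom(120, 1, 0.5) == 1)
    p <- bivariate_compare(cohort, "flag")$p
    if (p < 0.05) rejected <- rejected + 1
  }
  rate <- rejected / reps
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / reps))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("crude odds ratio equals cross-product arithmetic with Woolf CI", {
  expect_equal(crude_odds_ratio(1, 1, 1, 1)$or, 1)
  expect_equal(crude_odds_ratio(10, 5, 2, 4)$or, 4)
  # documentation-by-sex counts from the printed descriptive table
  or <- crude_odds_ratio(124243, 160025, 176457, 239895)
  expect_equal(or$or, 1.0556, tolerance = 1e-4)
  woolf <- exp(log(or$or) + c(-1, 1) * qnorm(0.975) *
                 sqrt(1 / 124243 + 1 / 160025 + 1 / 176457 + 1 / 239895))
  expect_equal(c(or$ci_low, or$ci_high), woolf, tolerance = 1e-12)
  z <- crude_odds_ratio(5, 0, 3, 7)
  expect_true(z$corrected)
  expect_equal(z$or, (5.5 * 7.5) / (0.5 * 3.5))
  expect_error(crude_odds_ratio(-1, 2, 3, 4), "non-negative")
})

test_that("documentation and risk models recover generator effects", {
  ex <- simulate_extract(sim_config(n_patients = 60000, n_providers = 120,
                                    seed = 33))
  cohort <- build_cohort(ex, age_cut = 50.7, provider_age_cut = 49.6)
  dm <- fit_documentation_model(cohort, unadjusted = FALSE)
  t <- dm$terms
  expect_identical(nrow(t), 10L)
  truth <- c(male = 1.09, age_over_mean = 1.26, rural = 1.00,
             high_visits = 1.11, depression = 1.11, diabetes = 0.95,
             hypertension = 1.07, osteoarthritis = 1.01,
             provider_male = 0.90, provider_age_over_mean = 1.09)
  for (tm in names(truth)) {
    row <- t[t$term == tm, ]
    expect_lt(abs(log(row$adjusted_or) - log(truth[[tm]])), 0.15,
              label = paste("doc", tm))
  }
  rm2 <- fit_risk_model(cohort, unadjusted = FALSE)
  expect_identical(nrow(rm2$terms), 8L)
  expect_identical(rm2$outcome,
                   "heightened alcohol-related risk (heavy or past)")
  # denominator excludes unknowns
  expect_identical(rm2$n_used,
                   sum(!is.na(cohort$category) &
                         cohort$category != "UNKNOWN"))
  male_or <- rm2$terms$adjusted_or[rm2$terms$term == "male"]
  expect_lt(abs(log(male_or) - log(3.27)), 0.25)
})

test_that("model wrappers refuse degenerate outcomes and missing terms", {
  ex <- make_mini_extract()
  cohort <- build_cohort(ex)
  # only 3 classified patients, outcome nearly constant cluster structure
  broken <- cohort
  broken$heightened_risk[!is.na(broken$heightened_risk)] <- FALSE
  expect_error(fit_risk_model(broken), "degenerate")
  nocol <- as.data.frame(cohort)
  nocol$depression <- NULL
  expect_error(fit_documentation_model(nocol), "lacks model terms")
})

test_that("unadjusted columns come from single-term clustered fits", {
  ex <- simulate_extract(sim_config(n_patients = 8000, n_providers = 40,
                                    seed = 44))
  cohort <- build_cohort(ex)
  dm <- fit_documentation_model(cohort)
  expect_true(all(c("unadjusted_or", "unadjusted_ci_low",
                    "unadjusted_ci_high") %in% names(dm$terms)))
  # cross-check one term against a directly fitted single-covariate GEE
  dat <- as.data.frame(cohort)
  dat$rural <- !dat$urban
  dat$.y <- as.numeric(dat$documented)
  single <- tidy_gee(gee_logit(.y ~ male, dat, id = "provider_id"))
  expect_equal(dm$terms$unadjusted_or[dm$terms$term == "male"],
               single$or[single$term == "maleTRUE"], tolerance = 1e-8)
})

test_that("report writes the expected sections with half-up rounding", {
  expect_identical(round_half_up(43.577), 43.6)
  expect_identical(round_half_up(43.55), 43.6)  # half rounds up
  expect_identical(round_half_up(1.005, 2), 1.01)
  ex <- simulate_extract(sim_config(n_patients = 6000, n_providers = 30,
                                    seed = 50))
  cohort <- build_cohort(ex)
  prev <- prevalence_table(cohort)
  bivs <- list(bivariate_compare(cohort, "male"),
               bivariate_compare(cohort, "hypertension"))
  models <- list(fit_documentation_model(cohort, unadjusted = FALSE),
                 fit_risk_model(cohort, unadjusted = FALSE))
  out <- withr::local_tempdir()
  write_report(prev, bivs, models, out)
  res <- read.csv(file.path(out, "results.csv"))
  secs <- unique(res$section)
  expect_identical(sum(secs == "prevalence"), 1L)
  expect_identical(sum(startsWith(secs, "bivariate:")), 2L)
  expect_identical(sum(startsWith(secs, "model:")), 2L)
  expect_true(file.exists(file.path(out, "report.txt")))
  # prevalence-only report still works
  out2 <- withr::local_tempdir()
  write_report(prev, list(), list(), out2)
  res2 <- read.csv(file.path(out2, "results.csv"))
  expect_identical(unique(res2$section), "prevalence")
})
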