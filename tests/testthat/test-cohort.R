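test_that("eligibility applies the adult filter and the half-open window", {
  ex <- make_mini_extract()
  elig <- select_eligible(ex$patients, ex$encounters)
  # P3 is 17.9 at the last in-window encounter; P5's only visit is 2014-12-31
  expect_identical(as.integer(elig), c(1L, 2L, 4L, 6L))
  # right endpoint exclusive: a 2018-01-01 encounter does not qualify
  enc <- rbind(ex$encounters,
               data.frame(encounter_id = 99L, patient_id = 5L,
                          provider_id = 2L, date = "2018-01-01"))
  expect_false(5L %in% select_eligible(ex$patients, enc))
  enc$date[enc$encounter_id == 99] <- "2017-12-31"
  expect_true(5L %in% select_eligible(ex$patients, enc))
})

test_that("eligibility matches a brute-force row scan on random extracts", {
  set.seed(31)
  n <- 300
  win <- as.Date(c("2015-01-01", "2018-01-01"))
  patients <- data.frame(
    patient_id = 1:n,
    birth_date = format(as.Date("1998-06-01") +
                          sample(-25000:1500, n, TRUE)))
  encounters <- data.frame(
    encounter_id = 1:(3 * n),
    patient_id = sample(n, 3 * n, TRUE),
    date = format(as.Date("2014-01-01") + sample(0:1800, 3 * n, TRUE)))
  got <- select_eligible(patients, encounters, win)
  # oracle: per-patient loop, no shared code with the implementation
  want <- c()
  for (p in 1:n) {
    d <- as.Date(encounters$date[encounters$patient_id == p])
    d <- d[d >= win[1] & d < win[2]]
    if (!length(d)) next
    age <- as.numeric(max(d) - as.Date(patients$birth_date[p])) / 365.25
    if (age >= 18) want <- c(want, p)
  }
  expect_identical(as.integer(got), as.integer(sort(want)))
})

test_that("unparseable encounter dates are excluded with a warning", {
  ex <- make_mini_extract()
  ex$encounters$date[2] <- "junk-date"
  expect_warning(elig <- select_eligible(ex$patients, ex$encounters),
                 "unparseable")
  expect_identical(attr(elig, "n_bad_dates"), 1L)
  expect_true(1L %in% elig)  # P1 still has an in-window 2015 visit
})

test_that("urban rule is inclusive at 100,000 with missingness flagged", {
  expect_identical(derive_urban(c(100000, 99999, 2500000, NA)),
                   c(TRUE, FALSE, TRUE, NA))
})

test_that("visit split takes the median across window years, cut at >3", {
  mk <- function(counts_by_year) {
    data.frame(patient_id = 1L,
               date = unlist(lapply(seq_along(counts_by_year), function(i)
                 rep(sprintf("%d-06-15", 2014 + i), counts_by_year[i]))))
  }
  v1 <- derive_visit_split(mk(c(2, 3, 4)))
  expect_equal(v1$visits_per_year_median, 3)
  expect_false(v1$high_visits)
  v2 <- derive_visit_split(mk(c(4, 4, 6)))
  expect_equal(v2$visits_per_year_median, 4)
  expect_true(v2$high_visits)
  # a year with no visits counts as zero
  v3 <- derive_visit_split(mk(c(0, 0, 5)))
  expect_equal(v3$visits_per_year_median, 0)
})

test_that("visit split equals an independent median recomputation", {
  set.seed(17)
  n <- 100
  rows <- list()
  truth <- numeric(n)
  for (p in 1:n) {
    counts <- rpois(3, 4)
    truth[p] <- sort(counts)[2]
    for (y in 1:3) {
      if (counts[y] > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = p,
          date = sprintf("%d-%02d-10", 2014 + y, sample(12, counts[y],
                                                        TRUE)))
      }
    }
  }
  enc <- do.call(rbind, rows)
  vs <- derive_visit_split(enc)
  present <- unique(enc$patient_id)
  expect_equal(vs$visits_per_year_median[match(present, vs$patient_id)],
               truth[present])
})

test_that("assembled cohort satisfies every row invariant", {
  ex <- make_mini_extract()
  cohort <- build_cohort(ex)
  expect_s3_class(cohort, "alcodoc_cohort")
  expect_identical(cohort$patient_id, c(1L, 2L, 4L, 6L))
  expect_true(all(cohort$age_years >= 18))
  # P1 moderate -> documented, not heightened risk
  expect_true(cohort$documented[1])
  expect_identical(cohort$category[1], "MODERATE")
  expect_false(cohort$heightened_risk[1])
  # P2's most recent note is the recovery note -> PAST -> heightened risk
  expect_identical(cohort$category[2], "PAST")
  expect_true(cohort$heightened_risk[2])
  # P4 has no note at all
  expect_false(cohort$documented[3])
  expect_true(is.na(cohort$category[3]))
  expect_true(is.na(cohort$heightened_risk[3]))
  # P6 unknown text: documented but outside the risk denominator
  expect_true(cohort$documented[4])
  expect_identical(cohort$category[4], "UNKNOWN")
  expect_true(is.na(cohort$heightened_risk[4]))
  expect_true(is.na(cohort$urban[4]))  # missing CMA population
  # provider covariates propagate
  expect_identical(cohort$provider_male, c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(cohort$provider_is_fp, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("the unknown-documentation switch moves patients out entirely", {
  ex <- make_mini_extract()
  cohort <- build_cohort(ex, unknown_counts_as_documented = FALSE)
  expect_false(cohort$documented[cohort$patient_id == 6])
  expect_true(is.na(cohort$category[cohort$patient_id == 6]))
})

test_that("age dichotomization matches direct computation at a forced cut", {
  ex <- simulate_extract(sim_config(n_patients = 2000, n_providers = 10,
                                    seed = 14))
  cohort <- build_cohort(ex, age_cut = 50.7, provider_age_cut = 49.6)
  expect_identical(attr(cohort, "age_cut"), 50.7)
  expect_equal(mean(cohort$age_over_mean),
               mean(cohort$age_years > 50.7))
  # default: observed patient-weighted mean
  cohort2 <- build_cohort(ex)
  expect_equal(attr(cohort2, "age_cut"), mean(cohort2$age_years))
  expect_identical(cohort2$age_over_mean,
                   cohort2$age_years > mean(cohort2$age_years))
})

test_that("denominator accounting holds: documented = classified + unknown", {
  ex <- simulate_extract(sim_config(n_patients = 5000, n_providers = 25,
                                    seed = 6))
  cohort <- build_cohort(ex)
  n_doc <- sum(cohort$documented)
  n_unknown <- sum(cohort$category == "UNKNOWN", na.rm = TRUE)
  n_classified <- sum(!is.na(cohort$category) &
                        cohort$category != "UNKNOWN")
  expect_identical(n_doc, n_classified + n_unknown)
  pt <- prevalence_table(cohort)
  expect_identical(unname(sum(pt$counts)), pt$classified_total)
  expect_identical(pt$documented_total,
                   pt$classified_total + pt$unclassified_count)
})

test_that("eligibility is monotone in encounters", {
  ex <- make_mini_extract()
  base <- select_eligible(ex$patients, ex$encounters)
  # adding an encounter can only add patients
  more <- rbind(ex$encounters,
                data.frame(encounter_id = 50L, patient_id = 3L,
                           provider_id = 1L, date = "2019-06-01"))
  expect_true(all(base %in% select_eligible(ex$patients, more)))
  # removing encounters can only remove patients
  fewer <- ex$encounters[ex$encounters$patient_id != 2L, ]
  expect_true(all(select_eligible(ex$patients, fewer) %in% base))
})

test_that("cohort assembly is deterministic on a fixed extract", {
  ex <- make_mini_extract()
  a <- build_cohort(ex)
  b <- build_cohort(ex)
  expect_identical(a, b)
})
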