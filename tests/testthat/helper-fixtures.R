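# Fixtures are built in code; nothing is read from disk.

# A hand-written extract: 6 patients / 2 providers with known properties.
#  P1 adult, documented moderate; P2 adult, past (two notes, recency matters);
#  P3 17.9y at last encounter (ineligible); P4 adult, no documentation;
#  P5 adult but only out-of-window encounter (ineligible);
#  P6 adult, unknown-text documentation.
make_mini_extract <- function() {
  patients <- data.frame(
    patient_id = 1:6,
    provider_id = c(1L, 1L, 1L, 2L, 2L, 2L),
    sex = c("M", "F", "M", "F", "M", "F"),
    birth_date = c("1970-06-15", "1950-01-01", "2000-01-20",
                   "1988-03-03", "1975-07-07", "1940-11-11"),
    cma_population = c(500000L, 5000L, 150000L, 99999L, 100000L, NA),
    stringsAsFactors = FALSE)
  providers <- data.frame(
    provider_id = 1:2,
    sex = c("F", "M"),
    birth_date = c("1980-05-05", "1955-09-09"),
    provider_type = c("FP", "NP"),
    stringsAsFactors = FALSE)
  encounters <- data.frame(
    encounter_id = 1:9,
    patient_id = c(1L, 1L, 2L, 2L, 3L, 4L, 5L, 6L, 6L),
    provider_id = c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L),
    date = c("2015-02-01", "2016-06-30", "2015-03-15", "2017-10-01",
             "2017-12-01", "2016-01-05", "2014-12-31", "2015-05-20",
             "2016-08-08"),
    stringsAsFactors = FALSE)
  conditions <- data.frame(
    patient_id = 1:6,
    depression = c(0L, 1L, 0L, 0L, 0L, 1L),
    diabetes = c(1L, 0L, 0L, 0L, 0L, 0L),
    hypertension = c(0L, 1L, 0L, 1L, 0L, 1L),
    osteoarthritis = c(0L, 0L, 0L, 0L, 0L, 1L),
    copd = 0L, dementia = 0L, epilepsy = 0L, parkinsons = 0L,
    stringsAsFactors = FALSE)
  riskfactor <- data.frame(
    patient_id = c(1L, 2L, 2L, 6L),
    date = c("2016-06-30", "2016-01-01", "2017-10-01", "2016-08-08"),
    text = c("6 drinks per week", "20 drinks/week",
             "quit drinking, recovered", "father was an alcoholic"),
    stringsAsFactors = FALSE)
  list(patients = patients, providers = providers, encounters = encounters,
       conditions = conditions, riskfactor = riskfactor)
}

# Cohort data frame reproducing the published Table 1/Table 2 margins:
# 700,620 patients, 284,268 documented (270,276 classified + 13,992
# unknown), category counts and male counts per the printed tables.
make_printed_cohort <- function() {
  counts <- c(NONE = 57712L, LIGHT = 117779L, MODERATE = 82178L,
              HEAVY = 8088L, PAST = 4519L)
  n_unknown <- 13992L
  n_undoc <- 416352L
  male_doc <- 124243L
  male_undoc <- 176457L
  n_doc <- sum(counts) + n_unknown
  category <- c(rep(names(counts), counts), rep("UNKNOWN", n_unknown),
                rep(NA_character_, n_undoc))
  documented <- c(rep(TRUE, n_doc), rep(FALSE, n_undoc))
  male <- c(rep(c(TRUE, FALSE), c(male_doc, n_doc - male_doc)),
            rep(c(TRUE, FALSE), c(male_undoc, n_undoc - male_undoc)))
  data.frame(patient_id = seq_along(category), documented = documented,
             category = category, male = male, stringsAsFactors = FALSE)
}
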