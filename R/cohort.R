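#' Select eligible patients: adults with an in-window encounter
#'
#' Eligibility requires age >= 18 years (computed at the patient's last
#' encounter inside the half-open window) and at least one encounter with a
#' date in `[start, end)`. Rows with unparseable encounter dates are
#' excluded with a warning and counted in the `n_bad_dates` attribute.
#'
#' @param patients data frame with `patient_id`, `birth_date`.
#' @param encounters data frame with `patient_id`, `date`.
#' @param window character or Date length-2, half-open `[start, end)`.
#' @return sorted, duplicate-free integer/character vector of eligible
#'   patient ids, with attribute `n_bad_dates`.
#' @export
select_eligible <- function(patients, encounters,
                            window = c("2015-01-01", "2018-01-01")) {
  win <- as.Date(window)
  d <- parse_iso_date(encounters$date, validate = TRUE)
  bad <- is.na(d) & !is.na(encounters$date)
  if (any(bad)) {
    warning(sum(bad), " encounter rows with unparseable dates excluded")
  }
  inwin <- !is.na(d) & d >= as.integer(win[1]) & d < as.integer(win[2])
  pid <- encounters$patient_id[inwin]
  dint <- d[inwin]
  if (!length(pid)) {
    out <- patients$patient_id[0]
    attr(out, "n_bad_dates") <- sum(bad)
    return(out)
  }
  agg <- data.table::data.table(pid = pid, d = dint)
  agg <- agg[, list(last = max(d)), keyby = "pid"]
  birth <- parse_iso_date(
    patients$birth_date[match(agg$pid, patients$patient_id)])
  age <- (agg$last - birth) / 365.25
  out <- sort(agg$pid[!is.na(age) & age >= 18])
  attr(out, "n_bad_dates") <- sum(bad)
  out
}

#' Urban residency from CMA population
#'
#' Urban means residence in a census metropolitan area of at least 100,000
#' people. Missing population yields `NA` (flagged; such patients drop out
#' of residency-adjusted models listwise).
#'
#' @param cma_population numeric vector of area populations.
#' @return logical vector with `NA` where population is missing.
#' @examples
#' derive_urban(c(100000, 99999, NA))  # TRUE FALSE NA
#' @export
derive_urban <- function(cma_population) {
  as.numeric(cma_population) >= 100000
}

#' Median annual visit count and the >3 visits/year split
#'
#' Counts encounters per calendar year of the window for each patient
#' (years without visits count as zero), takes the per-patient median, and
#' dichotomizes at more than 3 visits a year.
#'
#' @param encounters data frame with `patient_id`, `date`.
#' @param window half-open `[start, end)`; must span at least one whole
#'   year.
#' @return data frame: `patient_id`, `visits_per_year_median`,
#'   `high_visits`.
#' @export
derive_visit_split <- function(encounters,
                               window = c("2015-01-01", "2018-01-01")) {
  win <- as.Date(window)
  years <- as.integer(format(win[1], "%Y")):(as.integer(format(win[2] - 1,
                                                               "%Y")))
  if (as.numeric(win[2] - win[1]) < 365) {
    stop_data("window must span at least one whole year")
  }
  d <- parse_iso_date(encounters$date)
  inwin <- !is.na(d) & d >= as.integer(win[1]) & d < as.integer(win[2])
  pid <- encounters$patient_id[inwin]
  if (!length(pid)) {
    stop_data("no in-window encounters; eligible patients must have >= 1")
  }
  yr <- as.integer(substr(as.character(encounters$date), 1, 4))[inwin]
  tab <- data.table::data.table(pid = pid, yr = yr)
  tab <- tab[, list(n = .N), keyby = c("pid", "yr")]
  wide <- data.table::dcast(tab, pid ~ yr, value.var = "n", fill = 0L)
  for (y in setdiff(as.character(years), names(wide))) wide[[y]] <- 0L
  m <- as.matrix(wide[, as.character(years), with = FALSE])
  med <- if (length(years) == 3) {
    m[, 1] + m[, 2] + m[, 3] - pmax(m[, 1], m[, 2], m[, 3]) -
      pmin(m[, 1], m[, 2], m[, 3])
  } else {
    apply(m, 1, stats::median)
  }
  data.frame(patient_id = wide$pid, visits_per_year_median = med,
             high_visits = med > 3, stringsAsFactors = FALSE)
}

#' Assemble the analysis-ready cohort table
#'
#' One row per eligible patient with every derived covariate the models
#' use: demographics, the urban flag, comorbidity indicators, the visit
#' split, the documentation indicator and resolved alcohol category, the
#' heightened-risk outcome (heavy or past drinker; absent for unclassified
#' or undocumented patients), and provider-level covariates.
#'
#' Age is dichotomized at the cohort's observed mean by default, or at a
#' supplied cut (the published cohort used 50.7 for patients and 49.6 for
#' providers). Classified patients who are not eligible are dropped and
#' counted in the `n_dropped_classified` attribute.
#'
#' @param eligible vector of eligible patient ids from [select_eligible()].
#' @param extract an `alcodoc_extract` (or list with `patients`,
#'   `providers`, `encounters`, `conditions`).
#' @param classified per-patient classification from [classify_table()].
#' @param window half-open study window.
#' @param age_cut,provider_age_cut dichotomization cuts in years; `NULL`
#'   (default) uses the observed patient-weighted mean.
#' @param unknown_counts_as_documented logical; if `TRUE` (default)
#'   patients whose only documentation is unclassifiable still count as
#'   documented, but stay out of the risk-model denominator.
#' @return data frame of class `alcodoc_cohort`.
#' @export
assemble_cohort <- function(eligible, extract, classified,
                            window = c("2015-01-01", "2018-01-01"),
                            age_cut = NULL, provider_age_cut = NULL,
                            unknown_counts_as_documented = TRUE) {
  pats <- extract$patients
  provs <- extract$providers
  conds <- extract$conditions
  encs <- extract$encounters
  win <- as.Date(window)

  idx <- match(eligible, pats$patient_id)
  if (anyNA(idx)) stop_data("eligible ids missing from patients table")

  # age at last in-window encounter
  d <- parse_iso_date(encs$date)
  inwin <- !is.na(d) & d >= as.integer(win[1]) & d < as.integer(win[2])
  agg <- data.table::data.table(pid = encs$patient_id[inwin],
                                d = d[inwin])
  agg <- agg[, list(last = max(d)), keyby = "pid"]
  last_enc <- agg$last[match(eligible, agg$pid)]
  birth <- parse_iso_date(pats$birth_date[idx])
  age_years <- (last_enc - birth) / 365.25

  vs <- derive_visit_split(encs, window)
  vrow <- match(eligible, vs$patient_id)

  cidx <- match(eligible, conds$patient_id)
  flag <- function(nm) {
    if (is.null(conds[[nm]])) rep(FALSE, length(eligible)) else
      as.logical(conds[[nm]][cidx]) %in% TRUE
  }

  pidx <- match(pats$provider_id[idx], provs$provider_id)
  prov_age <- (as.numeric(win[2] - 1) -
                 as.numeric(as.Date(provs$birth_date[pidx]))) / 365.25

  krow <- match(eligible, classified$patient_id)
  n_dropped_classified <- sum(!classified$patient_id %in% eligible)
  category <- classified$label[krow]
  documented <- !is.na(category)
  if (!unknown_counts_as_documented) {
    documented[!is.na(category) & category == "UNKNOWN"] <- FALSE
    category[!is.na(category) & category == "UNKNOWN"] <- NA_character_
  }
  heightened_risk <- ifelse(is.na(category) | category == "UNKNOWN",
                            NA, category %in% c("HEAVY", "PAST"))

  a_cut <- age_cut %||% mean(age_years, na.rm = TRUE)
  p_cut <- provider_age_cut %||% mean(prov_age, na.rm = TRUE)

  cohort <- data.frame(
    patient_id = as.vector(eligible),
    provider_id = pats$provider_id[idx],
    male = pats$sex[idx] == "M",
    age_years = age_years,
    age_over_mean = age_years > a_cut,
    urban = derive_urban(pats$cma_population[idx]),
    depression = flag("depression"),
    diabetes = flag("diabetes"),
    hypertension = flag("hypertension"),
    osteoarthritis = flag("osteoarthritis"),
    copd = flag("copd"),
    dementia = flag("dementia"),
    epilepsy = flag("epilepsy"),
    parkinsons = flag("parkinsons"),
    visits_per_year_median = vs$visits_per_year_median[vrow],
    high_visits = vs$high_visits[vrow],
    documented = documented,
    category = category,
    heightened_risk = heightened_risk,
    provider_male = provs$sex[pidx] == "M",
    provider_age_over_mean = prov_age > p_cut,
    provider_is_fp = provs$provider_type[pidx] == "FP",
    stringsAsFactors = FALSE)
  attr(cohort, "age_cut") <- a_cut
  attr(cohort, "provider_age_cut") <- p_cut
  attr(cohort, "n_dropped_classified") <- n_dropped_classified
  class(cohort) <- c("alcodoc_cohort", "data.frame")
  check_cohort(cohort)
  cohort
}

#' Assert the cohort-row invariants over a whole table
#'
#' Checks: all ages >= 18; the heightened-risk flag is present exactly for
#' classified patients and equals membership in the heavy/past group;
#' undocumented patients carry no category.
#'
#' @param cohort an `alcodoc_cohort`.
#' @return the cohort, invisibly; stops on violation.
#' @export
check_cohort <- function(cohort) {
  if (any(cohort$age_years < 18, na.rm = TRUE)) {
    stop_data("cohort invariant violated: age under 18")
  }
  classified <- !is.na(cohort$category) & cohort$category != "UNKNOWN"
  if (!identical(classified, !is.na(cohort$heightened_risk))) {
    stop_data("cohort invariant violated: heightened_risk presence")
  }
  hr <- cohort$heightened_risk[classified]
  want <- cohort$category[classified] %in% c("HEAVY", "PAST")
  if (!identical(as.logical(hr), want)) {
    stop_data("cohort invariant violated: heightened_risk definition")
  }
  if (any(!cohort$documented & !is.na(cohort$category))) {
    stop_data("cohort invariant violated: category without documentation")
  }
  invisible(cohort)
}

#' Build a cohort straight from an extract
#'
#' Convenience wrapper: eligibility, classification resolution, and
#' covariate assembly in one call.
#'
#' @param extract an `alcodoc_extract`.
#' @param classified output of [classify_table()]; if `NULL`, the extract's
#'   risk-factor table is classified with `rules`.
#' @param rules rule set used when `classified` is `NULL`.
#' @inheritParams assemble_cohort
#' @return an `alcodoc_cohort`.
#' @export
build_cohort <- function(extract, classified = NULL,
                         rules = default_rules(),
                         window = c("2015-01-01", "2018-01-01"),
                         age_cut = NULL, provider_age_cut = NULL,
                         unknown_counts_as_documented = TRUE) {
  if (is.null(classified)) {
    classified <- classify_table(extract$riskfactor, rules)
  }
  eligible <- select_eligible(extract$patients, extract$encounters, window)
  assemble_cohort(eligible, extract, classified, window = window,
                  age_cut = age_cut, provider_age_cut = provider_age_cut,
                  unknown_counts_as_documented = unknown_counts_as_documented)
}
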